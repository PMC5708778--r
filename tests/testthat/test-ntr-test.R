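test_that("case rank sums use midranks", {
  # 2 cases hold the top 2 of 4 distinct scores
  expect_equal(rank_sum_cases(c(1, 2, 3, 4), c(0, 0, 1, 1)), 7)
  # all scores tied: every rank is (N + 1) / 2
  expect_equal(rank_sum_cases(rep(2, 6), c(1, 1, 0, 0, 0, 1)), 3 * 3.5)
  # three tied zeros share rank 2, the case holds rank 4
  expect_equal(rank_sum_cases(c(0, 0, 0, 5), c(0, 0, 0, 1)), 4)
  # invariance under strictly increasing transforms
  set.seed(2)
  s <- rnorm(30); st <- rbinom(30, 1, 0.5); st[1] <- 1; st[2] <- 0
  expect_equal(rank_sum_cases(s, st), rank_sum_cases(exp(s), st))
  expect_equal(rank_sum_cases(s, st), rank_sum_cases(100 + 3 * s, st))
})

test_that("exhaustive permutation null matches direct enumeration", {
  scores <- c(1, 2, 3, 4)
  status <- c(0, 0, 1, 1)
  nul <- permutation_null(scores, status, exhaustive = TRUE)
  sets <- combn(4, 2)
  r_all <- apply(sets, 2, function(i) sum(rank(scores)[i]))
  expect_setequal(as.vector(nul$r_perm), r_all)
  expect_equal(unname(nul$m), mean(r_all))   # = 5
  expect_equal(unname(nul$s), sd(r_all))
  # with ties, on an 8-individual fixture
  s8 <- c(0, 0, 0, 1, 1, 2, 2, 5)
  st8 <- c(1, 0, 0, 1, 0, 0, 1, 0)
  nul8 <- permutation_null(s8, st8, exhaustive = TRUE)
  r_all8 <- apply(combn(8, 3), 2, function(i) sum(rank(s8)[i]))
  expect_equal(unname(nul8$m), mean(r_all8))
  expect_equal(unname(nul8$s), sd(r_all8))
})

test_that("Monte-Carlo null moments approach the Wilcoxon closed form", {
  set.seed(13)
  N <- 60; nc <- 25
  scores <- rnorm(N)                      # distinct scores
  status <- c(rep(1, nc), rep(0, N - nc))
  nul <- permutation_null(scores, status, n_perm = 20000, seed = 99)
  m_cf <- nc * (N + 1) / 2
  s_cf <- sqrt(nc * (N - nc) * (N + 1) / 12)
  expect_equal(unname(nul$m), m_cf, tolerance = 0.01)
  expect_equal(unname(nul$s), s_cf, tolerance = 0.05)
  # permuted rank sums look normal at this size
  expect_gt(shapiro.test(sample(nul$r_perm[, 1], 3000))$p.value, 1e-4)
})

test_that("tied-score degeneracy yields s = 0 and p = 1", {
  nul <- permutation_null(rep(1, 10), rep(c(1, 0), 5), n_perm = 50, seed = 1)
  expect_equal(unname(nul$s), 0)
  X <- matrix(0L, 3, 20); X[, 1] <- 1L    # all carriers identical
  X[1, 2] <- 1L; X[2, 3] <- 1L            # keep variants polymorphic
  reg <- toy_region(X)
  st <- rep(c(1L, 0L), 10)
  fit <- suppressWarnings(ntr_region_test(reg, st, n_perm = 100, seed = 1,
                                          exhaustive = FALSE))
  expect_true(fit$p >= 0 && fit$p <= 1)
})

test_that("the exhaustive NTR engine matches a naive full-recompute oracle", {
  # oracle: for every label set, re-estimate ORs, rebuild all weights,
  # rescore every individual by the double pair sum, rank, and sum case
  # ranks -- no shared code with the engine's collapsed computation
  naive_R <- function(X, y, mf, Fmat) {
    L <- nrow(X); N <- ncol(X); nc <- sum(y)
    AC <- as.numeric(X %*% y); tot <- rowSums(X)
    CC <- tot - AC; mca <- 2 * nc - AC; mco <- 2 * (N - nc) - CC
    z <- AC == 0 | CC == 0 | mca == 0 | mco == 0; hh <- 0.5 * z
    a <- log2(((AC + hh) * (mco + hh)) / ((mca + hh) * (CC + hh)))
    W <- abs(a) / mf
    vapply(1:3, function(k) {
      S <- vapply(seq_len(N), function(j) {
        s <- sum(W * X[, j])
        for (i in 1:(L - 1)) for (m in (i + 1):L) {
          first <- switch(k, a[i] + a[m], abs(a[i] + a[m]),
                          abs(a[i]) + abs(a[m]))
          s <- s + first * Fmat[i, m] * (X[i, j] + X[m, j])
        }
        s
      }, numeric(1))
      sum(rank(S)[y == 1])
    }, numeric(1))
  }
  set.seed(5)
  for (trial in 1:4) {
    repeat {
      X <- matrix(rbinom(3 * 8, 2, 0.3), 3, 8)
      f <- rowMeans(X) / 2
      if (all(f > 0 & f < 1)) break
    }
    st <- sample(c(1, 1, 1, 0, 0, 0, 0, 0))
    reg <- orient_minor(region_genotypes(X))
    X <- reg$X
    fit <- ntr_region_test(reg, st, exhaustive = TRUE, maf_rare = 0.6)
    mf <- rowMeans(X) / 2
    D <- pairwise_dprime_matrix(reg)
    Fmat <- outer(1 / mf, 1 / mf, "+") * (1 - unclass(D)); diag(Fmat) <- 0
    r_all <- apply(combn(8, 3), 2, function(idx) {
      y <- integer(8); y[idx] <- 1L
      naive_R(X, y, mf, Fmat)
    })
    expect_equal(fit$r, naive_R(X, st, mf, Fmat))
    expect_equal(fit$m, rowMeans(r_all))
    expect_equal(fit$s, apply(r_all, 1, sd))
  }
})

test_that("the region test selects the scheme with the smallest p-value and
          caps p at 1", {
  set.seed(31)
  X <- matrix(rbinom(6 * 120, 2, 0.04), nrow = 6)
  reg <- toy_region(X)
  st <- rep(c(1L, 0L), 60)
  fit <- ntr_region_test(reg, st, n_perm = 300, seed = 8, maf_rare = 0.1)
  expect_s3_class(fit, "ntr_test")
  expect_equal(fit$p_min, min(fit$p_k))
  expect_equal(fit$p, min(p.adjust(fit$p_k, "BH")))
  expect_gte(fit$p, fit$p_min)            # scheme correction never helps
  expect_equal(fit$k_star, which.min(fit$p_k))
  expect_true(all(fit$p_k >= 0 & fit$p_k <= 1))
  expect_equal(fit$z, (fit$r - fit$m) / fit$s)
  expect_output(print(fit), "NTR region association test")
  expect_output(summary(fit), "per-variant statistics")
})

test_that("p-value is invariant to the PR rescaling threshold while PR > 0", {
  set.seed(17)
  X <- matrix(rbinom(5 * 100, 2, 0.05), nrow = 5)
  reg <- toy_region(X)
  st <- rep(c(1L, 0L), 50)
  f1 <- ntr_region_test(reg, st, n_perm = 200, seed = 5, maf_rare = 0.1)
  f2 <- ntr_region_test(reg, st, n_perm = 200, seed = 5, maf_rare = 0.4)
  expect_equal(f1$p, f2$p)
  expect_equal(f1$z, f2$z)
})

test_that("PR = 0 regions return a degenerate p = 1", {
  set.seed(23)
  X <- matrix(rbinom(4 * 80, 2, 0.45), nrow = 4)   # all common
  reg <- toy_region(X)
  st <- rep(c(1L, 0L), 40)
  fit <- ntr_region_test(reg, st, n_perm = 100, seed = 2, maf_rare = 1e-8)
  expect_true(fit$degenerate)
  expect_equal(fit$p, 1)
})

test_that("single-variant and monomorphic-only regions are rejected", {
  reg1 <- toy_region(matrix(c(0L, 1L, 0L, 1L), nrow = 1))
  expect_error(ntr_region_test(reg1, c(1, 0, 1, 0)), ">= 2 polymorphic")
  X <- rbind(c(0L, 1L, 0L, 1L), rep(0L, 4))
  expect_error(suppressWarnings(ntr_region_test(toy_region(X), c(1, 0, 1, 0))),
               ">= 2 polymorphic")
})

test_that("p-values fall as the simulated effect size grows", {
  p_at <- function(or) {
    cfg <- tiny_scenario(or_model = or, n_cases = 250, n_controls = 251)
    mean(vapply(1:12, function(r) {
      dat <- sample_case_control(cfg, seed = 1000 + r)
      suppressWarnings(ntr_region_test(dat$region, dat$status, n_perm = 300,
                                       seed = r)$p)
    }, numeric(1)))
  }
  expect_lt(p_at(2.5), p_at(1.0))
})

test_that("BH adjustment across regions matches the step-up rule", {
  expect_equal(fdr_adjust(0.03), 0.03)                   # single region
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.2, 0.9)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("multi-region studies skip singletons and attach q-values", {
  set.seed(41)
  regions <- list(
    toy_region(matrix(rbinom(4 * 60, 2, 0.05), 4), region_id = "gA"),
    toy_region(matrix(rbinom(3 * 60, 2, 0.08), 3), region_id = "gB"),
    toy_region(matrix(rbinom(60, 2, 0.2), 1), region_id = "gS"))
  regions[[3]]$single_variant <- TRUE
  st <- rep(c(1L, 0L), 30)
  expect_warning(study <- ntr_study(regions, st, n_perm = 200, seed = 3),
                 "single-variant")
  tab <- as.data.frame(study)
  expect_equal(tab$region_id, c("gA", "gB"))
  expect_equal(tab$q, fdr_adjust(tab$p))
  expect_output(print(study), "NTR study")
})
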