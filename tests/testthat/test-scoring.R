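test_that("MAF estimation counts pooled minor alleles and rejects
          monomorphic variants", {
  reg <- toy_region(rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 0L, 0L, 1L)))
  mf <- estimate_maf(reg)
  expect_equal(unname(mf), c(0.5, 0.125))
  expect_error(estimate_maf(toy_region(rbind(z = c(0L, 0L, 0L, 0L)))),
               "monomorphic")
  # missing genotypes leave the denominator
  regm <- toy_region(rbind(a = c(0L, 1L, NA, 1L)))
  expect_equal(unname(estimate_maf(regm)), 2 / 6)
})

test_that("allelic odds ratios match hand cross-products, with Haldane
          correction on zero cells", {
  # case alleles 20/180, control alleles 10/190
  g_case <- c(rep(2L, 5), rep(1L, 10), rep(0L, 85))
  g_ctl <- c(rep(2L, 2), rep(1L, 6), rep(0L, 92))
  reg <- toy_region(matrix(c(g_case, g_ctl), nrow = 1))
  status <- rep(c(1L, 0L), each = 100)
  expect_equal(unname(estimate_or(reg, status)), (20 * 190) / (180 * 10),
               tolerance = 1e-12)
  # identical allele frequencies: OR = 1 and weight 0
  reg2 <- toy_region(matrix(rep(c(0L, 1L), 10), nrow = 1))
  st2 <- rep(c(1L, 0L), each = 10)
  expect_equal(unname(estimate_or(reg2, st2)), 1)
  expect_equal(variant_stats(reg2, st2)$w, 0)
  # zero cell: case alleles 3/197, control 0/200
  g_case3 <- c(rep(1L, 3), rep(0L, 97))
  g_ctl3 <- rep(0L, 100)
  reg3 <- toy_region(matrix(c(g_case3, g_ctl3), nrow = 1))
  expect_equal(unname(estimate_or(reg3, status)),
               (3.5 * 200.5) / (197.5 * 0.5), tolerance = 1e-12)
})

test_that("main-effect weights are |log2 OR| / MAF", {
  expect_equal(main_weights(0.01, 2), 100)
  expect_equal(main_weights(0.3, 1), 0)
  expect_equal(main_weights(0.25, 0.5), 4)
})

test_that("pair weights match hand arithmetic and the direction conventions", {
  st <- structure(data.frame(variant = c("a", "b"), mf = c(0.1, 0.1),
                             or_ = c(2, 0.5), w = main_weights(c(0.1, 0.1),
                                                              c(2, 0.5))),
                  class = c("variant_stats", "data.frame"))
  ld0 <- diag(2); class(ld0) <- c("ld_matrix", class(ld0))
  pw <- pair_weights(st, ld0)
  # opposite directions cancel in schemes 1-2 but not 3
  expect_equal(pw$w_pair[[1]][1, 2], 0)
  expect_equal(pw$w_pair[[2]][1, 2], 0)
  expect_equal(pw$w_pair[[3]][1, 2], 40)
  # complete LD zeroes all schemes
  ld1 <- matrix(1, 2, 2)
  pw1 <- pair_weights(st, ld1)
  for (k in 1:3) expect_equal(pw1$w_pair[[k]][1, 2], 0)
  # same direction, D' = 0.5: all three agree at 200
  st2 <- st; st2$or_ <- c(2, 2); st2$mf <- c(0.01, 0.01)
  ldh <- matrix(c(1, 0.5, 0.5, 1), 2)
  pw2 <- pair_weights(st2, ldh)
  for (k in 1:3) expect_equal(pw2$w_pair[[k]][1, 2], 200)
})

test_that("pair-weight magnitudes obey |W1| = |W2| <= W3 on random inputs", {
  set.seed(21)
  for (i in 1:100) {
    L <- sample(2:6, 1)
    st <- data.frame(variant = paste0("v", 1:L),
                     mf = runif(L, 0.005, 0.5),
                     or_ = exp(rnorm(L, 0, 0.7)))
    st$w <- main_weights(st$mf, st$or_)
    D <- matrix(runif(L * L), L, L); D <- (D + t(D)) / 2; diag(D) <- 1
    pw <- pair_weights(st, D)
    expect_equal(abs(pw$w_pair[[1]]), abs(pw$w_pair[[2]]), tolerance = 1e-12)
    expect_true(all(pw$w_pair[[3]] >= abs(pw$w_pair[[1]]) - 1e-12))
    expect_true(all(pw$w_pair[[3]] >= 0))
    for (k in 1:3) expect_equal(pw$w_pair[[k]], t(pw$w_pair[[k]]))
  }
})

test_that("genetic scores follow the weighted-sum formula with PR scaling", {
  # L = 2, W = (2, 4), W12(1) = 1, PR = 0.5, X_j = (1, 2) -> S = 6.5
  st <- data.frame(variant = c("a", "b"), mf = c(0.005, 0.02),
                   or_ = c(2, 2), w = c(2, 4))
  pw <- list(w_pair = list(matrix(c(0, 1, 1, 0), 2),
                           matrix(c(0, 1, 1, 0), 2),
                           matrix(c(0, 1, 1, 0), 2)),
             ld = diag(2))
  class(pw) <- "pair_weight_set"
  reg <- toy_region(matrix(c(1L, 2L, 0L, 0L), nrow = 2))
  sc <- genetic_scores(reg, st, pw, maf_rare = 0.01)
  expect_equal(sc$pr, 0.5)
  expect_equal(unname(sc$s[1, ]), rep(6.5, 3))
  # an individual with no minor alleles scores 0
  expect_equal(unname(sc$s[2, ]), rep(0, 3))
  # PR rescaling: doubling PR doubles scores, ranks unchanged
  sc2 <- genetic_scores(reg, st, pw, maf_rare = 0.1)   # PR = 1
  expect_equal(sc2$pr, 1)
  expect_equal(sc2$s, 2 * sc$s)
  expect_equal(apply(sc2$s, 2, rank), apply(sc$s, 2, rank))
})

test_that("one-direction odds ratios make the three score schemes coincide", {
  set.seed(4)
  X <- matrix(rbinom(5 * 80, 2, 0.1), nrow = 5)
  reg <- toy_region(X)
  status <- rep(c(1L, 0L), 40)
  st <- variant_stats(reg, status)
  st$or_ <- pmax(st$or_, 1.0001)       # force one shared direction
  st$w <- main_weights(st$mf, st$or_)
  D <- pairwise_dprime_matrix(reg)
  pw <- pair_weights(st, D)
  sc <- genetic_scores(reg, st, pw)
  expect_equal(sc$s[, 1], sc$s[, 2], tolerance = 1e-10)
  expect_equal(sc$s[, 2], sc$s[, 3], tolerance = 1e-10)
})

test_that("PR = 0 degenerates every score to zero", {
  X <- matrix(rbinom(3 * 40, 2, 0.4), nrow = 3)
  reg <- toy_region(X)
  status <- rep(c(1L, 0L), 20)
  st <- variant_stats(reg, status)
  pw <- pair_weights(st, pairwise_dprime_matrix(reg))
  sc <- genetic_scores(reg, st, pw, maf_rare = 1e-6)
  expect_true(sc$degenerate)
  expect_true(all(sc$s == 0))
})

test_that("per-variant stats and scores export to TSV", {
  X <- matrix(rbinom(3 * 40, 2, 0.2), nrow = 3)
  reg <- toy_region(X)
  status <- rep(c(1L, 0L), 20)
  st <- variant_stats(reg, status)
  pw <- pair_weights(st, pairwise_dprime_matrix(reg))
  sc <- genetic_scores(reg, st, pw)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_scoring_tsv(st, sc, f1, f2)
  expect_equal(nrow(read.delim(f1)), 3L)
  expect_equal(nrow(read.delim(f2)), 40L)
})
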