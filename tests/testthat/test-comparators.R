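test_that("CMC collapses rare variants and agrees with a Fisher oracle on a
          carrier-only toy", {
  set.seed(51)
  n <- 600
  status <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(0L, 3, n)
  carriers <- sample(which(status == 1L), 12)       # rare carriers, cases only
  X[1, carriers[1:6]] <- 1L
  X[2, carriers[7:12]] <- 1L
  X[3, ] <- rbinom(n, 2, 0.3)                        # one common variant
  res <- cmc_test(toy_region(X), status, maf_threshold = 0.05)
  expect_lt(res$p, 0.01)
  expect_equal(res$details$n_collapsed, 2)
  expect_equal(res$details$df, 2)                    # indicator + 1 common
  carrier <- as.integer(colSums(X[1:2, ]) > 0)
  fisher_p <- fisher.test(table(carrier, status))$p.value
  expect_lt(fisher_p, 0.01)                          # oracle agrees on signif.
  # all-common region reduces to the multivariate logistic LRT
  Xc <- matrix(rbinom(2 * n, 2, 0.3), 2, n)
  res_c <- cmc_test(toy_region(Xc), status, maf_threshold = 0.01)
  expect_equal(res_c$details$n_collapsed, 0)
  expect_equal(res_c$details$df, 2)
  fit1 <- glm(status ~ t(Xc), family = binomial())
  fit0 <- glm(status ~ 1, family = binomial())
  lrt <- as.numeric(2 * (logLik(fit1) - logLik(fit0)))
  expect_equal(res_c$statistic, lrt, tolerance = 1e-8)
  # no usable predictors -> degenerate p = 1
  X0 <- matrix(0L, 2, 8); X0[1, 1] <- 1L; X0[2, 2] <- 1L
  res0 <- cmc_test(toy_region(X0), rep(c(1L, 0L), 4), maf_threshold = 0.5)
  expect_true(res0$p <= 1)
})

test_that("WSS weights favour variants absent from controls and the
          permutation agrees with exhaustive enumeration", {
  set.seed(52)
  n <- 100
  status <- rep(c(1L, 0L), each = n / 2)
  X <- rbind(rbinom(n, 2, 0.1),
             c(rbinom(n / 2, 2, 0.1), rep(0L, n / 2)))   # absent in controls
  reg <- orient_minor(toy_region(X))
  ctl <- status == 0
  q <- (rowSums(reg$X[, ctl]) + 1) / (2 * sum(ctl) + 2)
  w <- sqrt(n * q * (1 - q))
  expect_lt(w[2], w[1])              # rarer in controls -> smaller w, more weight
  # 6-individual fixture: exhaustive null moments equal direct enumeration
  X6 <- matrix(c(0, 1, 0, 2, 0, 1,
                 1, 0, 0, 1, 0, 0), nrow = 2, byrow = TRUE)
  st6 <- c(1, 1, 1, 0, 0, 0)
  res6 <- wss_test(toy_region(X6), st6, exhaustive = TRUE)
  reg6 <- orient_minor(toy_region(X6))
  # oracle re-derives control weights for every label set, by hand
  rs_oracle <- function(cases) {
    ctl <- setdiff(1:6, cases)
    q6 <- (rowSums(reg6$X[, ctl]) + 1) / (2 * 3 + 2)
    w6 <- sqrt(6 * q6 * (1 - q6))
    sc6 <- as.numeric(crossprod(reg6$X, 1 / w6))
    sum(rank(sc6)[cases])
  }
  r_all <- apply(combn(6, 3), 2, rs_oracle)
  z_oracle <- (rs_oracle(which(st6 == 1)) - mean(r_all)) / sd(r_all)
  expect_equal(res6$statistic, z_oracle, tolerance = 1e-10)
  expect_equal(res6$p, pnorm(z_oracle, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("SKAT reduces to the 1-df score test on a single variant", {
  set.seed(53)
  n <- 400
  status <- rep(c(1L, 0L), each = n / 2)
  x <- rbinom(n, 2, 0.2)
  reg <- toy_region(matrix(x, 1))
  res <- skat_test(reg, status, weights_beta = c(1, 1))  # flat weight
  mu <- mean(status); v <- mu * (1 - mu)
  u <- sum((x - mean(x)) * (status - mu))
  z2 <- u^2 / (v * sum((x - mean(x))^2))
  expect_equal(res$p, pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("SKAT Liu and Imhof p-values agree to first order and rank the
          evidence identically", {
  set.seed(54)
  X <- matrix(rbinom(6 * 300, 2, 0.05), nrow = 6)
  status <- rep(c(1L, 0L), 150)
  reg <- toy_region(X)
  p_liu <- skat_test(reg, status, method = "liu")$p
  p_imhof <- skat_test(reg, status, method = "imhof")$p
  expect_equal(p_liu, p_imhof, tolerance = 0.05)
})

test_that("SKAT-O spans SKAT and the burden test across its rho grid", {
  set.seed(55)
  X <- matrix(rbinom(5 * 400, 2, 0.08), nrow = 5)
  status <- rep(c(1L, 0L), 200)
  reg <- toy_region(X)
  so <- skat_o_test(reg, status)
  sk <- skat_test(reg, status)
  # at rho = 0 the per-rho p-value is SKAT's
  expect_equal(so$details$p_rho[1], sk$p, tolerance = 1e-6)
  expect_true(so$p >= 0 && so$p <= 1)
  # analytic combination is consistent with the permutation fallback
  so_perm <- skat_o_test(reg, status, method = "permutation",
                         n_perm = 600, seed = 5)
  expect_equal(so$p, so_perm$p, tolerance = 0.08)
})

test_that("the trend test matches the textbook statistic and the logistic
          score test", {
  # identical genotype distributions: statistic 0, p 1
  g <- rep(c(0L, 1L, 1L, 2L), 10)
  st <- rep(c(1L, 0L), 20)
  res0 <- trend_test(rep(g, 2)[1:40], rep(c(1L, 0L), each = 20))
  # construct counts (10,20,10) in both groups
  gg <- c(rep(0L, 10), rep(1L, 20), rep(2L, 10), rep(0L, 10), rep(1L, 20),
          rep(2L, 10))
  ss <- rep(c(1L, 0L), each = 40)
  resf <- trend_test(gg, ss)
  expect_equal(resf$statistic, 0, tolerance = 1e-12)
  expect_equal(resf$p, 1)
  # dose-effect toy against the hand formula
  g2 <- c(rep(0L, 30), rep(1L, 25), rep(2L, 15), rep(0L, 40), rep(1L, 20),
          rep(2L, 5))
  s2 <- rep(c(1L, 0L), c(70, 65))
  res2 <- trend_test(g2, s2)
  n_case <- c(30, 25, 15); n_tot <- c(70, 45, 20); sc <- 0:2
  N <- sum(n_tot); C <- sum(n_case)
  num <- sum(sc * (n_case - n_tot * C / N))
  pbar <- C / N
  den <- pbar * (1 - pbar) * (sum(sc^2 * n_tot) - sum(sc * n_tot)^2 / N)
  expect_equal(res2$statistic, num^2 / den, tolerance = 1e-8)
  # equivalence to the logistic score (Rao) test
  rao <- anova(glm(s2 ~ 1, family = binomial),
               glm(s2 ~ g2, family = binomial), test = "Rao")
  expect_equal(res2$statistic, rao$Rao[2], tolerance = 1e-6)
  expect_equal(trend_test(rep(0L, 20), rep(c(1L, 0L), 10))$p, 1)
})
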