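comparator_result <- function(method, statistic, p, details = list()) {
  structure(list(method = method, statistic = statistic,
                 p = min(max(p, 0), 1), details = details),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("\t%s region test\n\nstatistic = %.4g, p-value = %.5g\n",
              toupper(x$method), x$statistic, x$p))
  invisible(x)
}

#' CMC (combined multivariate and collapsing) test
#'
#' Variants with pooled MAF below `maf_threshold` are collapsed into a
#' single carrier indicator (1 if the individual carries any rare minor
#' allele); common variants enter individually. Association is assessed by
#' a likelihood-ratio test of the joint logistic model against the
#' intercept-only null, with df = number of retained predictors.
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @param maf_threshold collapsing threshold (default 0.01).
#' @return A `comparator_result` (`details$df`, `details$n_collapsed`).
#' @export
cmc_test <- function(region, status, maf_threshold = 0.01) {
  status <- validate_status(status, ncol(region$X))
  region <- orient_minor(region)
  X <- region$X
  X[is.na(X)] <- 0L
  mf <- rowSums(X) / (2 * ncol(X))
  rare <- mf < maf_threshold & mf > 0
  common <- !rare & mf > 0
  preds <- NULL
  if (any(rare))
    preds <- cbind(collapsed = as.integer(colSums(X[rare, , drop = FALSE]) > 0))
  if (any(common))
    preds <- cbind(preds, t(X[common, , drop = FALSE]))
  if (!is.null(preds))
    preds <- preds[, apply(preds, 2L, function(v) stats::var(v) > 0),
                   drop = FALSE]
  if (is.null(preds) || ncol(preds) == 0L)
    return(comparator_result("cmc", 0, 1,
                             list(df = 0L, degenerate = TRUE)))
  fit1 <- stats::glm(status ~ preds, family = stats::binomial())
  fit0 <- stats::glm(status ~ 1, family = stats::binomial())
  lrt <- as.numeric(2 * (stats::logLik(fit1) - stats::logLik(fit0)))
  df <- ncol(preds)
  comparator_result("cmc", lrt, stats::pchisq(lrt, df, lower.tail = FALSE),
                    list(df = df, n_collapsed = sum(rare)))
}

#' WSS (weighted sum statistic) test
#'
#' Madsen-Browning burden test: each variant is weighted by
#' `w_i = sqrt(n_i q_i (1 - q_i))` with `q_i = (m_i^U + 1) / (2 n_i^U + 2)`
#' estimated from controls, so rarer-in-controls variants count more. The
#' per-individual score `sum_i X_ij / w_i` is ranked over the whole sample
#' and the case rank sum compared with its permutation null (one-sided,
#' excess burden in cases). Because the weights are estimated from the
#' controls, they are re-estimated under each permuted labeling, as in the
#' original method. Missing genotypes count as 0 minor alleles.
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @param exhaustive enumerate all label sets (tiny samples only).
#' @return A `comparator_result` (`statistic` = standardised rank sum z).
#' @export
wss_test <- function(region, status, n_perm = 1000L, seed = NULL,
                     exhaustive = FALSE) {
  status <- validate_status(status, ncol(region$X))
  region <- orient_minor(region)
  X <- region$X
  X[is.na(X)] <- 0L
  N <- ncol(X)
  nc <- sum(status == 1L)
  rank_sum <- function(y) {
    n_u <- N - sum(y)
    m_u <- as.numeric(X %*% (1 - y))
    q <- (m_u + 1) / (2 * n_u + 2)
    w <- sqrt(N * q * (1 - q))
    score <- as.numeric(crossprod(X, 1 / w))
    sum(rank(score, ties.method = "average")[y == 1])
  }
  r_obs <- rank_sum(status)
  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (choose(N, nc) > 5e4)
      stop("exhaustive enumeration infeasible: choose(N, n_cases) too large")
    r_perm <- apply(utils::combn(N, nc), 2L, function(idx) {
      y <- integer(N); y[idx] <- 1L
      rank_sum(y)
    })
  } else {
    r_perm <- vapply(seq_len(n_perm), function(b) {
      y <- integer(N); y[sample.int(N, nc)] <- 1L
      rank_sum(y)
    }, numeric(1))
  }
  m <- mean(r_perm); s <- stats::sd(r_perm)
  if (s == 0)
    return(comparator_result("wss", 0, 1, list(degenerate = TRUE)))
  z <- (r_obs - m) / s
  comparator_result("wss", z, stats::pnorm(z, lower.tail = FALSE),
                    list(m = m, s = s, r = r_obs))
}

#' Cochran-Armitage trend test for a single variant
#'
#' Additive-score (0, 1, 2) trend test on the case proportions across the
#' three genotype classes; equivalent to the score test of the simple
#' logistic regression on allele dosage.
#'
#' @param g genotype vector (0/1/2, `NA` dropped) for one variant.
#' @param status 0/1 phenotype vector.
#' @return A `comparator_result` (1-df chi-square statistic).
#' @export
trend_test <- function(g, status) {
  keep <- !is.na(g)
  g <- g[keep]; status <- validate_status(status[keep], sum(keep))
  n_tot <- tabulate(g + 1L, 3L)
  n_case <- tabulate(g[status == 1L] + 1L, 3L)
  nz <- n_tot > 0L
  if (sum(nz) < 2L || stats::var(g) == 0)
    return(comparator_result("trend", 0, 1, list(degenerate = TRUE)))
  tt <- suppressWarnings(
    stats::prop.trend.test(n_case[nz], n_tot[nz], score = (0:2)[nz]))
  comparator_result("trend", unname(tt$statistic), tt$p.value)
}
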