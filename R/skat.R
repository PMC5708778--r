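# Mixture-of-chi-squares tail probabilities ----------------------------------

# Liu et al. moment-matching survival function for Q ~ sum lambda_i chisq_1.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(1)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * sqrt(l + 2 * d)
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = d, lower.tail = FALSE)
}

# Liu parameters used to invert the per-rho null quantile for SKAT-O.
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2), mu_x = l + d,
       sigma_x = sqrt(2) * sqrt(l + 2 * d), l = l, d = d)
}

# Imhof numerical inversion of the characteristic function (exact up to
# quadrature error).
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     subdivisions = 2000L, rel.tol = 1e-8)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  min(max(0.5 + val / pi, 0), 1)
}

mixture_pvalue <- function(q, lambda, method = c("liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) return(1)
  if (method == "imhof") {
    p <- imhof_pvalue(q, lambda)
    if (!is.na(p) && p > 1e-12) return(p)   # fall back when quadrature fails
  }
  liu_pvalue(q, lambda)
}

# SKAT ------------------------------------------------------------------------

skat_prepare <- function(region, status, weights_beta) {
  status <- validate_status(status, ncol(region$X))
  region <- orient_minor(region)
  X <- region$X
  X[is.na(X)] <- 0L
  G <- t(X)                               # N x L dosage
  maf <- colSums(G) / (2 * nrow(G))
  w <- stats::dbeta(maf, weights_beta[1], weights_beta[2])
  mu <- mean(status)
  v <- mu * (1 - mu)
  res <- status - mu
  Gc <- sweep(G, 2L, colMeans(G))
  Zw <- sweep(Gc, 2L, w, "*")             # centered, weighted genotypes
  list(status = status, res = res, v = v, Zw = Zw, w = w, maf = maf)
}

#' SKAT variance-component region test
#'
#' Score statistic `Q = sum_i w_i^2 (sum_j X_ij (y_j - ybar))^2` under an
#' intercept-only logistic null, with Beta(MAF; a, b) density weights
#' (default Beta(1, 25), up-weighting rare variants). The null distribution
#' of Q is a mixture of 1-df chi-squares with eigenvalues from the weighted,
#' centred genotype kernel; the p-value uses Liu's moment matching
#' (`method = "liu"`, default) or Imhof's exact characteristic-function
#' inversion (`method = "imhof"`).
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @param weights_beta Beta density parameters for the MAF weights.
#' @param method p-value method, "liu" or "imhof".
#' @return A `comparator_result` (`statistic` = Q; `details$lambda`).
#' @export
skat_test <- function(region, status, weights_beta = c(1, 25),
                      method = c("liu", "imhof")) {
  method <- match.arg(method)
  prep <- skat_prepare(region, status, weights_beta)
  u <- as.numeric(crossprod(prep$Zw, prep$res))
  Q <- sum(u^2)
  K <- crossprod(prep$Zw) * prep$v
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda))
    return(comparator_result("skat", Q, 1, list(degenerate = TRUE)))
  p <- mixture_pvalue(Q, lambda, method)
  comparator_result("skat", Q, p, list(lambda = lambda, maf = prep$maf))
}

#' SKAT-O optimal unified region test
#'
#' Evaluates the family `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` over a
#' grid of `rho` values in `[0, 1]` (11 equally spaced points by default),
#' computes each `Q_rho`'s mixture p-value, and combines the minimum across
#' the grid into an overall p-value by the one-dimensional integration of
#' the optimal-test construction (conditioning on the burden component,
#' which is chi-square 1). A label-permutation fallback
#' (`method = "permutation"`) estimates the null distribution of the min-p
#' statistic directly.
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @param weights_beta Beta density parameters for the MAF weights.
#' @param rho_grid mixing-parameter grid.
#' @param method "analytic" (default) or "permutation".
#' @param n_perm,seed permutation-fallback controls.
#' @return A `comparator_result` (`details$rho_min`, the grid value
#'   attaining the minimum p; `details$p_rho`).
#' @export
skat_o_test <- function(region, status, weights_beta = c(1, 25),
                        rho_grid = seq(0, 1, length.out = 11L),
                        method = c("analytic", "permutation"),
                        n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  prep <- skat_prepare(region, status, weights_beta)
  Zw <- prep$Zw; res <- prep$res; v <- prep$v
  L <- ncol(Zw)
  qstat <- function(r) {
    u <- as.numeric(crossprod(Zw, r))
    c(skat = sum(u^2), burden = sum(u)^2)
  }
  obs <- qstat(res)
  rho_adj <- pmin(rho_grid, 0.999)        # keep R_rho positive definite
  K <- crossprod(Zw) * v
  lambda_rho <- lapply(rho_adj, function(r) {
    R <- matrix(r, L, L); diag(R) <- 1
    C <- chol(R)
    ev <- eigen(C %*% K %*% t(C), symmetric = TRUE, only.values = TRUE)$values
    ev[ev > max(ev, 0) * 1e-10]
  })
  q_rho <- (1 - rho_grid) * obs["skat"] + rho_grid * obs["burden"]
  p_rho <- vapply(seq_along(rho_grid), function(i) {
    if (!length(lambda_rho[[i]])) return(1)
    mixture_pvalue(q_rho[i], lambda_rho[[i]], "liu")
  }, numeric(1))
  t_min <- min(p_rho)
  i_min <- which.min(p_rho)
  if (all(vapply(lambda_rho, length, integer(1)) == 0L))
    return(comparator_result("skat_o", obs["skat"], 1,
                             list(degenerate = TRUE)))
  if (method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    N <- length(prep$status); ncase <- sum(prep$status)
    tnull <- vapply(seq_len(n_perm), function(b) {
      y <- integer(N); y[sample.int(N, ncase)] <- 1L
      o <- qstat(y - mean(y))
      qs <- (1 - rho_grid) * o["skat"] + rho_grid * o["burden"]
      min(vapply(seq_along(rho_grid), function(i)
        mixture_pvalue(qs[i], lambda_rho[[i]], "liu"), numeric(1)))
    }, numeric(1))
    p <- (sum(tnull <= t_min) + 1) / (n_perm + 1)
    return(comparator_result("skat_o", t_min, p,
                             list(rho_min = rho_grid[i_min], p_rho = p_rho)))
  }
  p <- skat_o_integrate(Zw, v, rho_adj, p_rho)
  p <- min(p, t_min * length(rho_grid))   # Bonferroni guard on the grid
  comparator_result("skat_o", t_min, p,
                    list(rho_min = rho_grid[i_min], p_rho = p_rho))
}

# One-dimensional integration for the SKAT-O min-p combination: condition on
# the squared burden direction (a 1-df chi-square), express each rho's
# rejection boundary for the remaining mixture, and integrate.
skat_o_integrate <- function(Zw, v, rho_adj, p_rho) {
  Z1 <- Zw * sqrt(v)
  L <- ncol(Z1)
  z_mean <- rowMeans(Z1)
  zbar2 <- sum(z_mean^2)
  if (zbar2 <= 0) return(min(p_rho) * length(rho_adj))
  cof1 <- as.numeric(crossprod(z_mean, Z1)) / zbar2
  Z_it1 <- outer(z_mean, cof1)
  Z_it2 <- Z1 - Z_it1
  W22 <- crossprod(Z_it2)
  lambda <- eigen(W22, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) return(min(p_rho) * length(rho_adj))
  var_remain <- sum(crossprod(Z_it1) * W22) * 4
  mu_q <- sum(lambda)
  var_q <- 2 * sum(lambda^2) + var_remain
  df <- 12 / (12 * sum(lambda^4) / sum(lambda^2)^2)
  tau <- (L^2 * rho_adj + sum(cof1^2) * (1 - rho_adj)) * zbar2
  # per-rho null quantiles at the observed minimum p
  t_min <- min(p_rho)
  qmin <- vapply(seq_along(rho_adj), function(i) {
    R <- matrix(rho_adj[i], L, L); diag(R) <- 1
    C <- chol(R)
    ev <- eigen(C %*% (crossprod(Zw) * v) %*% t(C), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- ev[ev > max(ev, 0) * 1e-10]
    pa <- liu_params(ev)
    q0 <- stats::qchisq(t_min, df = pa$l, ncp = pa$d, lower.tail = FALSE)
    (q0 - pa$mu_x) / pa$sigma_x * pa$sigma_q + pa$mu_q
  }, numeric(1))
  integrand <- function(x) {
    vapply(x, function(xx) {
      qcond <- min((qmin - tau * xx) / (1 - rho_adj))
      tq <- (qcond - mu_q) / sqrt(var_q) * sqrt(2 * df) + df
      stats::pchisq(tq, df = df) * stats::dchisq(xx, df = 1)
    }, numeric(1))
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = 40,
                     subdivisions = 1000L, abs.tol = 1e-25)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(min(min(p_rho) * length(rho_adj), 1))
  min(max(1 - val, 0), 1)
}
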