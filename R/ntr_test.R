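#' Sum of case ranks of a score vector
#'
#' Ranks all individuals' scores together (midranks for ties) and sums the
#' ranks of the cases.
#'
#' @param scores numeric score vector over all individuals.
#' @param status 0/1 phenotype vector.
#' @return The rank sum `R`.
#' @export
rank_sum_cases <- function(scores, status) {
  status <- validate_status(status, length(scores))
  if (any(!is.finite(scores))) stop("scores must be finite")
  sum(rank(scores, ties.method = "average")[status == 1L])
}

#' Permutation null moments of the case rank sum for fixed scores
#'
#' Holds the scores (hence ranks) fixed and re-draws the case label set,
#' preserving the number of cases; returns the mean and standard deviation
#' (n - 1 denominator) of the permuted rank sums. With `exhaustive = TRUE`
#' all `choose(N, n_cases)` label sets are enumerated instead of sampled.
#' This is the building block for rank-sum tests whose scores do not depend
#' on the labels; the NTR statistic itself re-estimates its weights under
#' each permuted labeling (see [ntr_region_test()]).
#'
#' @param scores numeric vector or N x K matrix of score columns; all columns
#'   share the same permuted label sets.
#' @param status 0/1 phenotype vector.
#' @param n_perm number of Monte-Carlo permutations (ignored if exhaustive).
#' @param seed optional RNG seed.
#' @param exhaustive enumerate every label set (feasible for small N only).
#' @return List with `m`, `s` (per score column) and `r_perm`, the matrix of
#'   permuted rank sums (permutations x columns).
#' @export
permutation_null <- function(scores, status, n_perm = 1000L, seed = NULL,
                             exhaustive = FALSE) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  status <- validate_status(status, N)
  nc <- sum(status == 1L)
  rk <- apply(scores, 2L, rank, ties.method = "average")
  if (exhaustive) {
    if (choose(N, nc) > 5e4)
      stop("exhaustive enumeration infeasible: choose(N, n_cases) too large")
    sets <- utils::combn(N, nc)
    r_perm <- t(apply(sets, 2L, function(idx) colSums(rk[idx, , drop = FALSE])))
  } else {
    if (n_perm < 2L) stop("n_perm must be >= 2")
    if (!is.null(seed)) set.seed(seed)
    r_perm <- t(vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, nc)
      colSums(rk[idx, , drop = FALSE])
    }, numeric(ncol(rk))))
  }
  if (ncol(scores) == 1L) r_perm <- matrix(r_perm, ncol = 1L)
  list(m = colMeans(r_perm), s = apply(r_perm, 2L, stats::sd), r_perm = r_perm)
}

# Weighted midranks of every column of a score-by-permutation matrix in one
# ordering pass. Row g of S carries weight w[g] (its multiplicity in the
# full sample); the returned matrix holds, per column, the full-sample
# midrank shared by all w[g] individuals of profile g. Columns are affinely
# rescaled to (0, 1) (ties preserved exactly) and shifted by column offsets
# so values never interleave across columns; a single radix sort then
# assigns all midranks.
weighted_column_midranks <- function(S, w) {
  u <- nrow(S); B <- ncol(S); N <- sum(w)
  lo <- apply(S, 2L, min); hi <- apply(S, 2L, max)
  sc <- hi - lo
  sc[sc == 0] <- 1
  x <- as.vector((S - rep(lo, each = u)) / rep(sc, each = u) +
                   rep(2 * (seq_len(B) - 1), each = u))
  o <- order(x, method = "radix")
  cumw <- cumsum(w[(o - 1L) %% u + 1L])
  runs <- rle(x[o])$lengths
  ridx <- cumsum(runs)
  run_end <- cumw[ridx]
  run_w <- diff(c(0, run_end))
  col_of_run <- (o[ridx] - 1L) %/% u
  run_end <- run_end - col_of_run * N          # restart cumweight per column
  mid <- run_end - (run_w - 1) / 2
  r <- numeric(length(x))
  r[o] <- rep(mid, runs)
  matrix(r, u, B)
}

# ---------------------------------------------------------------------------
# NTR permutation engine.
#
# The NTR statistic is adaptive: its weights contain OR estimates taken from
# the analysed sample, so a valid permutation null must recompute the whole
# statistic (ORs -> weights -> scores -> ranks) under every permuted
# labeling. Pooled-sample quantities (MAF, D', hence the factor
# F_im = (1/MF_i + 1/MF_m)(1 - D'_im)) do not involve the labels and stay
# fixed.
#
# Individuals with identical genotype profiles have identical scores under
# every scheme and labeling, and non-carriers score exactly 0, so the sample
# collapses to unique carrier profiles plus a zero block. Permuting labels
# then reduces to a multivariate hypergeometric draw of per-profile case
# counts, and ranking reduces to weighted midranks over the profiles —
# distribution-identical to naive label permutation, at a fraction of the
# cost.
#
# X: L x N minor-allele counts, no NAs. Returns R statistics for the
# observed labels plus permutation moments, per scheme k = 1..3.
ntr_perm_engine <- function(X, status, mf, Fmat, n_perm, seed = NULL,
                            exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(X); N <- ncol(X)
  nc <- sum(status == 1L)
  carrier <- colSums(X) > 0L
  Nz <- N - sum(carrier)
  # collapse carriers to unique genotype profiles
  key <- apply(X[, carrier, drop = FALSE], 2L, paste, collapse = ",")
  pid <- match(key, unique(key))
  u <- max(pid)
  Xu <- X[, carrier, drop = FALSE][, match(seq_len(u), pid), drop = FALSE]
  n_g <- tabulate(pid, u)                  # profile multiplicities
  w_aug <- c(n_g, Nz)                      # + virtual zero-score profile
  tot <- as.numeric(Xu %*% n_g)            # pooled minor-allele counts
  F1 <- rowSums(Fmat)

  stat_fun <- function(Kcase) {
    # Kcase: u x B case counts per carrier profile
    B <- ncol(Kcase)
    k_b <- .colSums(Kcase, u, B)
    AC <- Xu %*% Kcase                     # minor alleles among cases
    CC <- tot - AC
    maj_ca <- 2 * nc - AC
    maj_co <- 2 * (N - nc) - CC
    zero <- AC == 0 | CC == 0 | maj_ca == 0 | maj_co == 0
    h <- 0.5 * zero
    a <- log2(((AC + h) * (maj_co + h)) / ((maj_ca + h) * (CC + h)))
    absa <- abs(a)
    W <- absa / mf
    s1r <- a * F1 + Fmat %*% a
    s3r <- absa * F1 + Fmat %*% absa
    s2r <- matrix(0, L, B)
    for (m in seq_len(L))
      s2r <- s2r + abs(a + rep(a[m, ], each = L)) * Fmat[, m]
    R_out <- matrix(0, B, 3L)
    for (k in 1:3) {
      Ck <- W + switch(k, s1r, s2r, s3r)
      S <- rbind(crossprod(Xu, Ck), 0)     # profile scores + zero block
      FullR <- weighted_column_midranks(S, w_aug)
      R_out[, k] <- .colSums(FullR[-(u + 1L), , drop = FALSE] * Kcase,
                             u, B) + FullR[u + 1L, ] * (nc - k_b)
    }
    R_out
  }

  k_obs <- vapply(seq_len(u), function(g)
    sum(status[carrier][pid == g] == 1L), integer(1))
  r_obs <- stat_fun(matrix(k_obs, ncol = 1L))[1L, ]

  if (exhaustive) {
    if (choose(N, nc) > 5e4)
      stop("exhaustive enumeration infeasible: choose(N, n_cases) too large")
    pid_full <- integer(N)
    pid_full[carrier] <- pid               # 0 = non-carrier
    Kcase <- apply(utils::combn(N, nc), 2L, function(idx)
      tabulate(pid_full[idx], u))
    Kcase <- matrix(Kcase, nrow = u)
  } else {
    # sequential conditional hypergeometric draws over the profiles
    Kcase <- matrix(0, u, n_perm)
    rem_draw <- rep.int(nc, n_perm)
    rem_pop <- N
    for (g in seq_len(u)) {
      Kcase[g, ] <- stats::rhyper(n_perm, n_g[g], rem_pop - n_g[g], rem_draw)
      rem_draw <- rem_draw - Kcase[g, ]
      rem_pop <- rem_pop - n_g[g]
    }
  }
  r_perm <- stat_fun(Kcase)
  list(r = r_obs, m = colMeans(r_perm), s = apply(r_perm, 2L, stats::sd),
       r_perm = r_perm)
}

#' Non-threshold rare-variant (NTR) region association test
#'
#' Tests a region of rare and/or common variants for case-control
#' association without a MAF threshold. Per-variant weights
#' `W_i = |log2 OR_i| / MF_i` and LD-penalised pair weights `W_im(k)`
#' (three direction-handling schemes, see [pair_weights()]) combine into
#' per-individual genetic scores `S_j(k)`; the sum of case ranks `R(k)` is
#' standardised against its permutation null to
#' `Z(k) = (R(k) - m(k)) / s(k)`, and each scheme's two-sided normal
#' p-value `p(k) = 2 * P(Z > |Z(k)|)` (capped at 1) is computed. The scheme
#' `k*` minimising `p(k)` is selected; because the minimum over the three
#' correlated schemes is anti-conservative on its own, the region-level
#' p-value `p` is the FDR-corrected minimum (Simes / minimum BH-adjusted
#' value over the three schemes). When the three schemes agree — as they do
#' whenever all effects point one way — the correction costs nothing and
#' `p = p(k*)`.
#'
#' Because the weights contain odds ratios estimated from the analysed
#' sample, each permutation re-estimates them under the permuted labels and
#' recomputes scores and ranks; only the label-free pooled quantities (MAF,
#' D') are held fixed. `m(k)` and `s(k)` are the mean and standard deviation
#' (n - 1 denominator) of the permuted rank sums. Missing genotypes are set
#' to 0 minor alleles at entry so observed and permuted statistics are the
#' same function of the data.
#'
#' Degenerate regions (no variant with `MAF < maf_rare`, so `PR = 0` and
#' every score vanishes, or all permuted rank sums tied) return `p = 1`
#' with `degenerate = TRUE`. Monomorphic variants are dropped with a
#' warning; at least two polymorphic variants are required.
#'
#' @param region a [region_genotypes] object (re-oriented internally so that
#'   counted alleles are pooled minor alleles).
#' @param status 0/1 phenotype vector over the region's individuals.
#' @param n_perm number of label permutations (default 1000).
#' @param seed optional RNG seed controlling the permutations.
#' @param maf_rare MAF threshold defining the rare-variant proportion PR.
#' @param ld_use haplotype-frequency source for D' ("auto": phased when
#'   stored, EM otherwise).
#' @param exhaustive enumerate all label sets instead of sampling (tiny N
#'   only).
#' @return Object of class `ntr_test`: `r`, `m`, `s`, `z` (length-3
#'   vectors), `p_k` (per-scheme two-sided p-values), `k_star`, `p_min`
#'   (`= p_k[k_star]`, the uncorrected selected-scheme value), `p` (the
#'   scheme-corrected region p-value), `pr`, `L`, `n_perm`, `seed`,
#'   `degenerate`, `stats`, `ld`.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(8 * 60, 2, 0.05), nrow = 8)
#' reg <- region_genotypes(X)
#' fit <- ntr_region_test(reg, rep(0:1, each = 30), n_perm = 200, seed = 1)
#' print(fit)
#' @export
ntr_region_test <- function(region, status, n_perm = 1000L, seed = NULL,
                            maf_rare = 0.01, ld_use = "auto",
                            exhaustive = FALSE) {
  stopifnot(inherits(region, "region_genotypes"))
  status <- validate_status(status, ncol(region$X))
  region <- orient_minor(region)
  region$X[is.na(region$X)] <- 0L          # missing = 0 minor alleles
  f <- rowMeans(region$X) / 2
  poly <- f > 0 & f < 1
  if (any(!poly)) {
    warning("dropping ", sum(!poly), " monomorphic variant(s) from region '",
            region$region_id, "'")
    region <- subset_region(region, poly)
  }
  L <- nrow(region$X)
  if (L < 2L) stop("NTR needs >= 2 polymorphic variants (region '",
                   region$region_id, "')")
  stats_ <- variant_stats(region, status)
  mf <- stats_$mf
  pr <- mean(mf < maf_rare)
  ld <- pairwise_dprime_matrix(region, use = ld_use)
  out <- list(region_id = region$region_id, L = L, pr = pr,
              n_perm = as.integer(n_perm), seed = seed, stats = stats_,
              ld = ld, maf_rare = maf_rare)
  if (pr == 0) {
    out <- c(out, list(r = rep(NA_real_, 3), m = rep(NA_real_, 3),
                       s = rep(NA_real_, 3), z = rep(NA_real_, 3),
                       p_k = rep(1, 3), k_star = NA_integer_, p_min = 1,
                       p = 1, degenerate = TRUE))
    class(out) <- "ntr_test"
    return(out)
  }
  inv <- 1 / mf
  Fmat <- outer(inv, inv, "+") * (1 - unclass(ld))
  diag(Fmat) <- 0
  eng <- ntr_perm_engine(region$X, status, mf, Fmat, n_perm = n_perm,
                         seed = seed, exhaustive = exhaustive)
  z <- (eng$r - eng$m) / eng$s
  z[eng$s == 0] <- NA_real_
  p_k <- ifelse(is.na(z), 1, pmin(2 * stats::pnorm(-abs(z)), 1))
  k_star <- which.min(p_k)
  p_corr <- min(stats::p.adjust(p_k, method = "BH"))
  out <- c(out, list(r = unname(eng$r), m = unname(eng$m), s = unname(eng$s),
                     z = unname(z), p_k = unname(p_k),
                     k_star = as.integer(k_star),
                     p_min = unname(p_k[k_star]), p = p_corr,
                     degenerate = all(is.na(z))))
  class(out) <- "ntr_test"
  out
}

subset_region <- function(region, keep) {
  idx <- if (is.logical(keep)) which(keep) else keep
  region$X <- region$X[idx, , drop = FALSE]
  if (!is.null(region$haplotypes))
    region$haplotypes <- region$haplotypes[idx, , drop = FALSE]
  for (fld in c("variant_ids", "positions", "chrom", "ref", "alt",
                "minor_allele"))
    region[[fld]] <- region[[fld]][idx]
  region$single_variant <- length(idx) == 1L
  region
}

#' @export
print.ntr_test <- function(x, ...) {
  cat("\tNTR region association test\n\n")
  cat(sprintf("region: %s   L = %d variants   PR = %.4g   permutations = %d\n",
              x$region_id, x$L, x$pr, x$n_perm))
  if (x$degenerate) {
    cat("degenerate region (PR = 0 or all rank sums tied): p = 1\n")
  } else {
    cat(sprintf("Z(k) = %s;  k* = %d, p(k*) = %.5g\n",
                paste(sprintf("%.3f", x$z), collapse = ", "), x$k_star,
                x$p_min))
    cat(sprintf("region p-value = %.5g  (scheme-corrected minimum)\n", x$p))
  }
  invisible(x)
}

#' @export
summary.ntr_test <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat("\nper-scheme rank sums:\n")
    print(data.frame(k = 1:3, R = object$r, m = object$m, s = object$s,
                     Z = object$z, p = object$p_k))
  }
  cat("\nper-variant statistics:\n")
  print(utils::head(object$stats, 10))
  invisible(object)
}

#' Multi-region study with FDR adjustment
#'
#' Runs [ntr_region_test()] (or a comparator via `method`) on every region
#' and adjusts the region p-values across the study by Benjamini-Hochberg.
#' Single-variant regions are skipped with a warning (the test requires at
#' least two variants).
#'
#' @param regions list of [region_genotypes] objects.
#' @param status 0/1 phenotype vector.
#' @param method one of "ntr", "cmc", "wss", "skat", "skat_o".
#' @param ... passed to the region test.
#' @return Object of class `ntr_study`: a data frame `table` with columns
#'   region_id, L, pr, p, q, degenerate, plus the list of per-region fits.
#' @export
ntr_study <- function(regions, status, method = "ntr", ...) {
  fits <- list()
  for (reg in regions) {
    if (isTRUE(reg$single_variant)) {
      warning("skipping single-variant region '", reg$region_id, "'")
      next
    }
    fits[[reg$region_id]] <-
      region_test(reg, status, method = method, ...)
  }
  if (!length(fits)) stop("no testable regions")
  p <- vapply(fits, function(f) f$p, numeric(1))
  tab <- data.frame(
    region_id = names(fits),
    L = vapply(fits, function(f) if (is.null(f$L)) NA_integer_ else f$L,
               integer(1)),
    pr = vapply(fits, function(f) if (is.null(f$pr)) NA_real_ else f$pr,
                numeric(1)),
    p = unname(p),
    q = unname(fdr_adjust(p)),
    degenerate = vapply(fits, function(f) isTRUE(f$degenerate), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits, method = method),
            class = "ntr_study")
}

#' @export
print.ntr_study <- function(x, ...) {
  cat(sprintf("NTR study: %d region(s), method = %s\n\n",
              nrow(x$table), x$method))
  print(x$table)
  invisible(x)
}

#' @export
as.data.frame.ntr_study <- function(x, ...) x$table

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR q-values for a vector of region p-values.
#'
#' @param p p-value vector.
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Uniform region-test dispatcher
#'
#' Shared entry point over NTR and the comparator tests, used by
#' [ntr_study()] and the command-line interface.
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @param method one of "ntr", "cmc", "wss", "skat", "skat_o".
#' @param ... method-specific arguments.
#' @return The method's result object (all carry `$p`).
#' @export
region_test <- function(region, status,
                        method = c("ntr", "cmc", "wss", "skat", "skat_o"),
                        ...) {
  method <- match.arg(method)
  switch(method,
         ntr = ntr_region_test(region, status, ...),
         cmc = cmc_test(region, status, ...),
         wss = wss_test(region, status, ...),
         skat = skat_test(region, status, ...),
         skat_o = skat_o_test(region, status, ...))
}
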