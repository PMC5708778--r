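#' Per-variant minor allele frequencies
#'
#' Pooled-sample (cases + controls) minor-allele frequency for each variant
#' in a region, with missing genotypes excluded from the denominator. A
#' controls-only estimate is available via `subset`.
#'
#' @param region a [region_genotypes] object (minor-allele oriented; see
#'   [orient_minor()]).
#' @param subset optional individual index (e.g. `status == 0`).
#' @return Numeric vector of frequencies in `(0, 1)`; errors on a
#'   monomorphic variant.
#' @export
estimate_maf <- function(region, subset = NULL) {
  X <- region$X
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  nn <- rowSums(!is.na(X))
  if (any(nn == 0L)) stop("variant with no non-missing genotypes")
  mf <- rowSums(X, na.rm = TRUE) / (2 * nn)
  if (any(mf == 0 | mf == 1))
    stop("monomorphic variant(s): ",
         paste(region$variant_ids[mf == 0 | mf == 1], collapse = ", "))
  stats::setNames(mf, region$variant_ids)
}

#' Per-variant allelic odds ratios
#'
#' Odds ratio of the minor allele from the 2x2 allele-count table
#' (minor/major x case/control), with the Haldane-Anscombe 0.5 continuity
#' correction applied to all four cells when any cell is zero.
#'
#' @param region a [region_genotypes] object.
#' @param status 0/1 phenotype vector.
#' @return Numeric vector of odds ratios (> 0).
#' @export
estimate_or <- function(region, status) {
  status <- validate_status(status, ncol(region$X))
  X <- region$X
  ca <- status == 1L
  a <- rowSums(X[, ca, drop = FALSE], na.rm = TRUE)                 # minor, cases
  b <- 2 * rowSums(!is.na(X[, ca, drop = FALSE])) - a               # major, cases
  c_ <- rowSums(X[, !ca, drop = FALSE], na.rm = TRUE)               # minor, controls
  d <- 2 * rowSums(!is.na(X[, !ca, drop = FALSE])) - c_             # major, controls
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c_[zero] <- c_[zero] + 0.5; d[zero] <- d[zero] + 0.5
  stats::setNames((a * d) / (b * c_), region$variant_ids)
}

#' Per-variant statistics feeding the genetic score
#'
#' Computes MAF, allelic OR and the main-effect weight
#' `W_i = |log2 OR_i| * (1 / MF_i)` for every variant.
#'
#' @inheritParams estimate_or
#' @param maf_subset optional individual index for the MAF estimate (default
#'   pooled sample).
#' @return A data frame of class `variant_stats` with columns `variant`,
#'   `mf`, `or_`, `w`.
#' @export
variant_stats <- function(region, status, maf_subset = NULL) {
  mf <- estimate_maf(region, subset = maf_subset)
  or_ <- estimate_or(region, status)
  structure(data.frame(variant = region$variant_ids, mf = unname(mf),
                       or_ = unname(or_), w = unname(main_weights(mf, or_)),
                       stringsAsFactors = FALSE),
            class = c("variant_stats", "data.frame"))
}

#' Main-effect weights
#'
#' `W_i = |log2 OR_i| / MF_i`: rarer variants and larger effects (in either
#' direction) are up-weighted; a null variant (OR = 1) gets weight 0.
#'
#' @param mf minor allele frequencies.
#' @param or_ allelic odds ratios.
#' @return Non-negative weight vector.
#' @export
main_weights <- function(mf, or_) abs(log2(or_)) / mf

#' Pairwise interaction weights
#'
#' The three pair-weight matrices, for variants i and m with
#' `a_i = log2 OR_i` and `f = (1/MF_i + 1/MF_m) * (1 - D'_im)`:
#' \describe{
#'   \item{k = 1}{`(a_i + a_m) * f` (signed sum; opposite directions cancel)}
#'   \item{k = 2}{`|a_i + a_m| * f`}
#'   \item{k = 3}{`(|a_i| + |a_m|) * f` (direction-blind)}
#' }
#' Schemes 1 and 2 share magnitudes; scheme 3 dominates both. Pairs in
#' complete LD (`D' = 1`) get weight 0 under every scheme, so tightly linked
#' variants do not double-count.
#'
#' @param stats a `variant_stats` data frame.
#' @param ld the matching `L x L` D' matrix.
#' @return A list of class `pair_weight_set` with elements `w_pair` (list of
#'   three symmetric matrices) and `ld`.
#' @export
pair_weights <- function(stats, ld) {
  L <- nrow(stats)
  if (!all(dim(ld) == L)) stop("LD matrix dimensions do not match variant stats")
  a <- log2(stats$or_)
  inv <- 1 / stats$mf
  f <- outer(inv, inv, "+") * (1 - unclass(ld))
  s1 <- outer(a, a, "+") * f
  s2 <- abs(outer(a, a, "+")) * f
  s3 <- outer(abs(a), abs(a), "+") * f
  diag(s1) <- 0; diag(s2) <- 0; diag(s3) <- 0
  structure(list(w_pair = list(s1, s2, s3), ld = ld),
            class = "pair_weight_set")
}

#' Per-individual genetic scores
#'
#' The region score of individual j under pair-weighting scheme k:
#' `S_j(k) = [ sum_i W_i X_ij + sum_{i<m} W_im(k) (X_ij + X_mj) ] * PR`,
#' where each unordered pair contributes once and `PR` is the proportion of
#' variants with `MAF < maf_rare`. Missing genotypes contribute 0.
#'
#' @param region a [region_genotypes] object.
#' @param stats a `variant_stats` data frame.
#' @param pairs a `pair_weight_set`.
#' @param maf_rare rarity threshold defining PR (default 0.01).
#' @return A list of class `score_set`: `s` (N x 3 score matrix), `pr`, and
#'   `degenerate` (TRUE when PR = 0, which zeroes every score).
#' @export
genetic_scores <- function(region, stats, pairs, maf_rare = 0.01) {
  X <- region$X
  X[is.na(X)] <- 0L
  pr <- mean(stats$mf < maf_rare)
  # sum_{i<m} W_im (X_i + X_m) = sum_i X_i * sum_{m != i} W_im
  s <- vapply(pairs$w_pair, function(Wk) {
    coef <- stats$w + rowSums(Wk)   # diag(Wk) = 0
    as.numeric(crossprod(X, coef)) * pr
  }, numeric(ncol(X)))
  colnames(s) <- paste0("k", 1:3)
  structure(list(s = s, pr = pr, degenerate = pr == 0), class = "score_set")
}

#' Export per-variant statistics and scores for audit
#'
#' @param stats a `variant_stats` data frame.
#' @param scores a `score_set`.
#' @param stats_path,scores_path output TSV paths (either may be `NULL`).
#' @return Invisibly `NULL`.
#' @export
write_scoring_tsv <- function(stats, scores = NULL, stats_path = NULL,
                              scores_path = NULL) {
  if (!is.null(stats_path))
    utils::write.table(stats, stats_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(scores_path) && !is.null(scores)) {
    df <- data.frame(individual = seq_len(nrow(scores$s)), scores$s,
                     check.names = FALSE)
    utils::write.table(df, scores_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
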