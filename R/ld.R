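#' Two-locus haplotype frequencies from phased haplotypes
#'
#' Counts the four haplotype classes formed by the alleles at two loci across
#' a set of phased haplotypes.
#'
#' @param hapA,hapB equal-length 0/1 allele vectors, one entry per haplotype.
#' @return A list of class `hap_freq_table` with elements `h` (2x2 matrix of
#'   haplotype proportions, rows = alleles 1/0 at locus A, columns = alleles
#'   1/0 at locus B), `p` and `q` (marginal allele proportions) and
#'   `degenerate` (TRUE when either locus is monomorphic).
#' @export
haplotype_freqs_phased <- function(hapA, hapB) {
  if (length(hapA) != length(hapB)) stop("haplotype vectors must have equal length")
  keep <- !(is.na(hapA) | is.na(hapB))
  hapA <- hapA[keep]; hapB <- hapB[keep]
  if (!length(hapA)) stop("no haplotypes to count")
  h <- matrix(0, 2, 2, dimnames = list(A = c("1", "0"), B = c("1", "0")))
  h["1", "1"] <- sum(hapA == 1 & hapB == 1)
  h["1", "0"] <- sum(hapA == 1 & hapB == 0)
  h["0", "1"] <- sum(hapA == 0 & hapB == 1)
  h["0", "0"] <- sum(hapA == 0 & hapB == 0)
  hap_freq_table(h / length(hapA))
}

hap_freq_table <- function(h) {
  p <- rowSums(h); q <- colSums(h)
  structure(list(h = h, p = p, q = q,
                 degenerate = any(p < .Machine$double.eps) ||
                   any(q < .Machine$double.eps)),
            class = "hap_freq_table")
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Maximum-likelihood haplotype proportions for two biallelic loci under
#' Hardy-Weinberg equilibrium, by expectation-maximisation over the
#' double-heterozygote phase ambiguity. Initialised at linkage equilibrium;
#' converges when the largest change in any haplotype frequency is below
#' `tol` or after `max_iter` iterations.
#'
#' @param gA,gB genotype vectors (minor-allele counts 0/1/2, `NA` allowed) on
#'   the same individuals.
#' @param tol,max_iter EM convergence tolerance and iteration cap.
#' @return A `hap_freq_table` (see [haplotype_freqs_phased()]).
#' @export
haplotype_freqs_em <- function(gA, gB, tol = 1e-10, max_iter = 1000L) {
  keep <- !(is.na(gA) | is.na(gB))
  gA <- gA[keep]; gB <- gB[keep]
  n <- length(gA)
  if (!n) stop("no individuals with genotypes at both loci")
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    h <- outer(c(pA, 1 - pA), c(pB, 1 - pB))
    dimnames(h) <- list(A = c("1", "0"), B = c("1", "0"))
    return(hap_freq_table(h))
  }
  # 3x3 genotype table; only (1,1) double heterozygotes have ambiguous phase
  tab <- table(factor(gA, 0:2), factor(gB, 0:2))
  n_dh <- tab["1", "1"]
  # unambiguous haplotype counts contributed by the other 8 cells:
  # individual with gA=a, gB=b (not both 1) carries known haplotypes.
  cnt <- function(i, j) tab[as.character(i), as.character(j)]
  base11 <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)            # hap (1,1)
  base10 <- 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0)            # hap (1,0)
  base01 <- 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2)            # hap (0,1)
  base00 <- 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0)            # hap (0,0)
  h11 <- pA * pB; h10 <- pA * (1 - pB); h01 <- (1 - pA) * pB
  h00 <- (1 - pA) * (1 - pB)
  total <- 2 * n
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between cis (11/00) and trans (10/01)
    denom <- h11 * h00 + h10 * h01
    w_cis <- if (denom > 0) h11 * h00 / denom else 0.5
    n11 <- base11 + n_dh * w_cis
    n00 <- base00 + n_dh * w_cis
    n10 <- base10 + n_dh * (1 - w_cis)
    n01 <- base01 + n_dh * (1 - w_cis)
    new <- c(n11, n10, n01, n00) / total
    delta <- max(abs(new - c(h11, h10, h01, h00)))
    h11 <- new[1]; h10 <- new[2]; h01 <- new[3]; h00 <- new[4]
    if (delta < tol) break
  }
  h <- matrix(c(h11, h01, h10, h00), 2, 2,
              dimnames = list(A = c("1", "0"), B = c("1", "0")))
  hap_freq_table(h)
}

#' Hedrick's multiallelic D'
#'
#' Normalised linkage disequilibrium `sum_i sum_m p_i q_m |D_im / D_max|`
#' with `D_im = h_im - p_i q_m` and `D_max = min(p_i q_m, (1-p_i)(1-q_m))`
#' when `D_im < 0`, `min(p_i (1-q_m), (1-p_i) q_m)` when `D_im > 0`. Cells
#' with `D_im = 0` contribute 0 (independence). For two biallelic loci every
#' cell has the same `|D/D_max|`, so this reduces to Lewontin's `|D'|`.
#'
#' @param table a `hap_freq_table`.
#' @return A value in `[0, 1]`.
#' @export
hedrick_dprime <- function(table) {
  if (inherits(table, "hap_freq_table")) {
    if (table$degenerate) stop("D' undefined: monomorphic locus")
    h <- table$h; p <- table$p; q <- table$q
  } else {
    h <- as.matrix(table); p <- rowSums(h); q <- colSums(h)
    if (abs(sum(h) - 1) > 1e-9) stop("haplotype proportions must sum to 1")
    if (any(p < .Machine$double.eps) || any(q < .Machine$double.eps))
      stop("D' undefined: monomorphic locus")
  }
  acc <- 0
  for (i in 1:2) for (m in 1:2) {
    D <- h[i, m] - p[i] * q[m]
    if (D == 0) next
    dmax <- if (D < 0) min(p[i] * q[m], (1 - p[i]) * (1 - q[m]))
            else        min(p[i] * (1 - q[m]), (1 - p[i]) * q[m])
    acc <- acc + p[i] * q[m] * abs(D / dmax)
  }
  min(max(acc, 0), 1)
}

#' Pairwise D' matrix for a region
#'
#' Hedrick's D' for every variant pair, from the stored phased haplotypes
#' when present (direct counting) or by EM phase reconstruction otherwise.
#' Pairs involving a monomorphic variant get `D' = 0` (flagged by warning)
#' so downstream pair weights stay finite; the diagonal is 1 by definition.
#'
#' @param region a [region_genotypes] object with `L >= 2` variants.
#' @param use `"auto"` (phased if available), `"phased"` or `"em"`.
#' @param subset optional logical/integer index of individuals (e.g. controls
#'   only) over which to estimate haplotype frequencies; default pooled.
#' @return A symmetric `L x L` matrix of class `ld_matrix`.
#' @export
pairwise_dprime_matrix <- function(region, use = c("auto", "phased", "em"),
                                   subset = NULL) {
  use <- match.arg(use)
  L <- nrow(region$X)
  if (L < 2L) stop("need at least 2 variants for an LD matrix")
  phased <- !is.null(region$haplotypes) && use != "em"
  if (use == "phased" && is.null(region$haplotypes))
    stop("no phased haplotypes stored")
  X <- region$X
  H <- region$haplotypes
  if (!is.null(subset)) {
    X <- X[, subset, drop = FALSE]
    if (!is.null(H)) {
      idx <- if (is.logical(subset)) which(subset) else subset
      H <- H[, as.vector(rbind(2L * idx - 1L, 2L * idx)), drop = FALSE]
    }
  }
  mono <- apply(X, 1L, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || sum(g) == 0L || sum(g) == 2L * length(g)
  })
  if (phased && !anyNA(H)) {
    D <- dprime_matrix_phased(H)
    D[mono, ] <- 0; D[, mono] <- 0
    diag(D) <- 1
  } else {
    D <- diag(1, L)
    for (i in 1:(L - 1L)) for (m in (i + 1L):L) {
      if (mono[i] || mono[m]) {
        D[i, m] <- D[m, i] <- 0
        next
      }
      tab <- if (phased) haplotype_freqs_phased(H[i, ], H[m, ])
             else haplotype_freqs_em(X[i, ], X[m, ])
      D[i, m] <- D[m, i] <- if (tab$degenerate) 0 else hedrick_dprime(tab)
    }
  }
  if (any(mono))
    warning("monomorphic variant(s): affected D' entries set to 0")
  dimnames(D) <- list(region$variant_ids, region$variant_ids)
  class(D) <- c("ld_matrix", class(D))
  D
}

# All-pairs Hedrick D' from a complete phased 0/1 haplotype matrix
# (L x 2N). One matrix product gives every pair's (1,1) haplotype count;
# for biallelic loci the |D/Dmax| ratio is shared by all four cells, so the
# Hedrick sum collapses to the classical |D'| computed elementwise.
dprime_matrix_phased <- function(H) {
  nh <- ncol(H)
  C11 <- tcrossprod(H) / nh
  p <- rowSums(H) / nh
  P <- outer(p, p)
  D <- C11 - P
  pos <- pmin(outer(p, 1 - p), outer(1 - p, p))
  neg <- pmin(P, outer(1 - p, 1 - p))
  dmax <- ifelse(D > 0, pos, neg)
  out <- ifelse(D == 0 | dmax <= 0, 0, abs(D / dmax))
  pmin(pmax(out, 0), 1)
}

#' Export an LD matrix as a long-format TSV
#'
#' @param ld an `ld_matrix` from [pairwise_dprime_matrix()].
#' @param path output file path.
#' @return Invisibly, the exported data frame.
#' @export
write_ld_tsv <- function(ld, path) {
  idx <- which(upper.tri(ld), arr.ind = TRUE)
  df <- data.frame(variant_i = rownames(ld)[idx[, 1]],
                   variant_j = colnames(ld)[idx[, 2]],
                   dprime = ld[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
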