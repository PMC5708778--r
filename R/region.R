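#' Region genotype container
#'
#' Bundles the minor-allele count matrix for one analysis region (a gene, a
#' haplotype block, a pathway) together with variant metadata and, when
#' available, the underlying phased haplotypes.
#'
#' @param X integer matrix of minor-allele counts with `L` rows (variants) and
#'   `N` columns (individuals); entries 0, 1, 2 or `NA`.
#' @param region_id character label for the region.
#' @param variant_ids character vector of variant labels (defaults to
#'   `rownames(X)` or `v1..vL`).
#' @param positions integer base-pair coordinates, one per variant.
#' @param chrom chromosome labels, one per variant (recycled from length 1).
#' @param ref,alt reference / alternate allele labels, one per variant.
#' @param minor_allele per-variant label of the allele being counted in `X`
#'   (the less frequent allele in the pooled sample).
#' @param haplotypes optional 0/1 matrix with `L` rows and `2N` columns;
#'   columns `2j-1` and `2j` are the two haplotypes of individual `j` and must
#'   sum to `X[, j]`.
#'
#' @return An object of class `region_genotypes`.
#' @export
region_genotypes <- function(X, region_id = "region", variant_ids = NULL,
                             positions = NULL, chrom = "1", ref = NULL,
                             alt = NULL, minor_allele = NULL,
                             haplotypes = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  L <- nrow(X)
  bad <- !(X %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  if (is.null(variant_ids)) {
    variant_ids <- if (!is.null(rownames(X))) rownames(X) else paste0("v", seq_len(L))
  }
  if (length(variant_ids) != L) stop("variant_ids length must equal nrow(X)")
  if (is.null(positions)) positions <- seq_len(L) * 1000L
  if (length(chrom) == 1L) chrom <- rep(chrom, L)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  if (is.null(minor_allele)) minor_allele <- alt
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != L || ncol(haplotypes) != 2L * ncol(X))
      stop("haplotypes must be L x 2N")
    hx <- haplotypes[, seq(1L, 2L * ncol(X), by = 2L), drop = FALSE] +
      haplotypes[, seq(2L, 2L * ncol(X), by = 2L), drop = FALSE]
    if (!identical(unname(hx), unname(X)))
      stop("haplotype pairs must sum to the genotype matrix")
  }
  rownames(X) <- variant_ids
  structure(list(
    region_id = region_id, variant_ids = unname(variant_ids),
    positions = unname(as.integer(positions)), chrom = unname(chrom),
    ref = unname(ref), alt = unname(alt),
    minor_allele = unname(minor_allele), X = X, haplotypes = haplotypes,
    single_variant = L == 1L
  ), class = "region_genotypes")
}

#' @export
print.region_genotypes <- function(x, ...) {
  cat(sprintf("Region '%s': %d variant(s) x %d individual(s)%s\n",
              x$region_id, nrow(x$X), ncol(x$X),
              if (is.null(x$haplotypes)) "" else " (phased)"))
  invisible(x)
}

#' @export
dim.region_genotypes <- function(x) dim(x$X)

#' Re-orient variants so the counted allele is the pooled minor allele
#'
#' Rows of `X` whose counted-allele frequency exceeds 0.5 in the pooled sample
#' are flipped (`X <- 2 - X`, haplotypes complemented, allele labels swapped)
#' so downstream frequencies satisfy `MAF <= 0.5`. Idempotent.
#'
#' @param region a [region_genotypes] object.
#' @return The re-oriented `region_genotypes`.
#' @export
orient_minor <- function(region) {
  f <- rowMeans(region$X, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) {
    region$X[flip, ] <- 2L - region$X[flip, ]
    if (!is.null(region$haplotypes))
      region$haplotypes[flip, ] <- 1L - region$haplotypes[flip, ]
    tmp <- region$minor_allele[flip]
    other <- ifelse(tmp == region$ref[flip], region$alt[flip], region$ref[flip])
    region$minor_allele[flip] <- other
  }
  region
}

validate_status <- function(status, n) {
  status <- as.integer(status)
  if (length(status) != n)
    stop("phenotype length (", length(status), ") != number of individuals (", n, ")")
  if (!all(status %in% c(0L, 1L))) stop("phenotype must be coded 0 (control) / 1 (case)")
  if (sum(status == 1L) < 1L || sum(status == 0L) < 1L)
    stop("need at least one case and one control")
  status
}
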