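#' Read case-control genotypes from VCF or PLINK files
#'
#' Loads a full dataset (all variants, all samples) as a single
#' [region_genotypes] plus a phenotype vector. Only biallelic SNPs are kept;
#' multi-allelic sites are dropped with a warning. The counted allele is the
#' pooled-sample minor allele (ties kept as read). Phased VCF genotypes
#' (`|` separators throughout) also populate the haplotype matrix.
#'
#' Phenotypes come from a two-column sidecar TSV (`sample_id`, `status` in
#' 0/1) for VCF input, or from .fam column 6 (1 = control, 2 = case) for
#' PLINK input; absent or unparsable phenotypes are an error ("phenotype
#' required").
#'
#' @param path VCF file path, or the PLINK prefix / any of the .bed/.bim/.fam
#'   paths.
#' @param format "vcf" or "plink".
#' @param phenotype_file sidecar phenotype TSV (required for VCF).
#' @return List with `genotypes` (a [region_genotypes] spanning all retained
#'   variants), `status` (0/1 integer vector) and `samples`.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink"),
                           phenotype_file = NULL) {
  format <- match.arg(format)
  if (format == "vcf") read_vcf_dataset(path, phenotype_file)
  else read_plink_dataset(path)
}

read_vcf_dataset <- function(path, phenotype_file) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("VCF parse error: ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi))
    warning("dropping ", sum(!bi), " multi-allelic site(s)")
  if (!any(bi)) stop("no biallelic variants")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  samples <- colnames(gt)
  phased <- all(grepl("|", gt, fixed = TRUE) | is.na(gt))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  alt_count <- matrix(as.integer(a1) + as.integer(a2), nrow = nrow(gt))
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], ":", fix[miss_id, "POS"])
  haps <- NULL
  if (phased) {
    n <- length(samples)
    haps <- matrix(0L, nrow(gt), 2L * n)
    haps[, seq(1L, 2L * n, 2L)] <- as.integer(a1)
    haps[, seq(2L, 2L * n, 2L)] <- as.integer(a2)
  }
  region <- region_genotypes(alt_count, region_id = "all",
                             variant_ids = ids,
                             positions = as.integer(fix[, "POS"]),
                             chrom = fix[, "CHROM"], ref = fix[, "REF"],
                             alt = fix[, "ALT"], minor_allele = fix[, "ALT"],
                             haplotypes = haps)
  region <- orient_minor(region)
  if (is.null(phenotype_file))
    stop("phenotype required: supply phenotype_file (sample_id, status TSV)")
  status <- read_phenotypes(phenotype_file, samples)
  list(genotypes = region, status = status, samples = samples)
}

#' Read a sample-phenotype sidecar TSV
#'
#' @param path TSV with header columns `sample_id` and `status` (0/1).
#' @param samples sample names, in genotype-column order.
#' @return Integer 0/1 vector aligned to `samples`.
#' @export
read_phenotypes <- function(path, samples) {
  if (!file.exists(path)) stop("phenotype required: file not found: ", path)
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(ph)))
    stop("phenotype file needs columns sample_id, status")
  idx <- match(samples, ph$sample_id)
  if (any(is.na(idx)))
    stop("phenotype required: missing status for sample(s) ",
         paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
  validate_status(ph$status[idx], length(samples))
}

read_plink_dataset <- function(path) {
  prefix <- sub("\\.(bed|bim|fam)$", "", path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("cannot read PLINK fileset: missing ", f)
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pid", "mid",
                                            "sex", "phen"))
  n <- nrow(fam_df); L <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = 3L + L * ceiling(n / 4))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed supported")
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes, little-endian within each byte:
  # 0 = hom A1 (2 copies of A1), 1 = missing, 2 = het, 3 = hom A2
  codes <- matrix(0L, nrow = 4L * bpv, ncol = L)
  bytes <- matrix(body, nrow = bpv, ncol = L)
  for (sh in 0:3)
    codes[seq(sh + 1L, 4L * bpv, by = 4L), ] <-
      bytes %/% (4L^sh) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA, 1L, 0L)          # A1-allele count per code 0..3
  X <- matrix(lut[codes + 1L], nrow = n)
  if (!all(fam_df$phen %in% c(1L, 2L)))
    stop("phenotype required: .fam column 6 must be 1 (control) / 2 (case)")
  region <- region_genotypes(t(X), region_id = "all",
                             variant_ids = bim_df$id,
                             positions = bim_df$pos, chrom = bim_df$chrom,
                             ref = bim_df$a2, alt = bim_df$a1,
                             minor_allele = bim_df$a1)
  region <- orient_minor(region)
  list(genotypes = region, status = as.integer(fam_df$phen == 2L),
       samples = fam_df$iid)
}

#' Write a region as a VCF 4.2 text file
#'
#' ALT is written as the counted (minor) allele so that re-reading with
#' [read_genotypes()] reproduces `X` exactly. Phased haplotypes, when
#' stored, are written with `|` separators.
#'
#' @param region a [region_genotypes] object.
#' @param path output path.
#' @param samples sample names (default `s1..sN`).
#' @return Invisibly, `path`.
#' @export
write_region_vcf <- function(region, path, samples = NULL) {
  n <- ncol(region$X)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  ref <- ifelse(region$minor_allele == region$ref, region$alt, region$ref)
  alt <- region$minor_allele
  sep <- if (is.null(region$haplotypes)) "/" else "|"
  gt_rows <- vapply(seq_len(nrow(region$X)), function(i) {
    if (is.null(region$haplotypes)) {
      g <- region$X[i, ]
      s <- c("0/0", "0/1", "1/1")[g + 1L]
      s[is.na(g)] <- "./."
    } else {
      h1 <- region$haplotypes[i, seq(1L, 2L * n, 2L)]
      h2 <- region$haplotypes[i, seq(2L, 2L * n, 2L)]
      s <- paste0(h1, "|", h2)
      s[is.na(h1) | is.na(h2)] <- ".|."
    }
    paste(s, collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ntr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  writeLines(paste(region$chrom, region$positions, region$variant_ids,
                   ref, alt, ".", "PASS", ".", "GT", gt_rows, sep = "\t"), con)
  invisible(path)
}

#' Hardy-Weinberg equilibrium test for one variant
#'
#' Chi-square goodness-of-fit with 1 df on the three genotype counts
#' (default), or the exact test summing the probabilities of heterozygote
#' counts no more likely than the observed one.
#'
#' @param g genotype vector (0/1/2, `NA` dropped).
#' @param method "chisq" or "exact".
#' @return p-value (`NA` for a monomorphic variant).
#' @export
hwe_test <- function(g, method = c("chisq", "exact")) {
  method <- match.arg(method)
  g <- g[!is.na(g)]
  n <- length(g)
  if (!n) return(NA_real_)
  n2 <- sum(g == 2L); n1 <- sum(g == 1L); n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(NA_real_)
  if (method == "chisq") {
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    hwe_exact(n1, 2 * n2 + n1, n)
  }
}

# Exact HWE p-value: probability mass over heterozygote counts compatible
# with the observed minor-allele count, summed over outcomes no more
# probable than the observed one.
hwe_exact <- function(n_het, n_minor, n) {
  parity <- n_minor %% 2L
  hets <- seq(parity, min(n_minor, 2L * n - n_minor), by = 2L)
  # P(h | n_minor, n) proportional to 2^h / (h! hom_min! hom_maj!)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lgamma(h + 1) - lgamma(hom_min + 1) - lgamma(hom_maj + 1)
  }, numeric(1))
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Quality-control filter
#'
#' Removes variants whose genotype call rate falls below `call_rate_min` or
#' whose Hardy-Weinberg p-value in controls falls below `hwe_alpha`.
#'
#' @param data list as returned by [read_genotypes()] (`genotypes`,
#'   `status`).
#' @param call_rate_min minimum fraction of non-missing genotypes
#'   (default 0.95).
#' @param hwe_alpha HWE p-value threshold (default 1e-4).
#' @param hwe_method "chisq" (1-df goodness of fit) or "exact".
#' @return List with filtered `genotypes`, `status`, and `report`, a data
#'   frame of removed variants with columns `variant`, `reason`, `value`.
#' @export
qc_filter <- function(data, call_rate_min = 0.95, hwe_alpha = 1e-4,
                      hwe_method = "chisq") {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1)
  region <- data$genotypes
  status <- validate_status(data$status, ncol(region$X))
  cr <- rowMeans(!is.na(region$X))
  hwe_p <- apply(region$X[, status == 0L, drop = FALSE], 1L, hwe_test,
                 method = hwe_method)
  fail_cr <- cr < call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  report <- rbind(
    data.frame(variant = region$variant_ids[fail_cr],
               reason = rep("call_rate", sum(fail_cr)),
               value = cr[fail_cr], stringsAsFactors = FALSE),
    data.frame(variant = region$variant_ids[fail_hwe & !fail_cr],
               reason = rep("hwe", sum(fail_hwe & !fail_cr)),
               value = hwe_p[fail_hwe & !fail_cr],
               stringsAsFactors = FALSE))
  keep <- !(fail_cr | fail_hwe)
  if (!any(keep)) warning("all variants removed by QC")
  list(genotypes = subset_region(region, keep), status = status,
       report = report)
}

#' Slice a dataset into analysis regions
#'
#' @param data list as returned by [read_genotypes()] / [qc_filter()].
#' @param region_spec either a data frame with columns `region_id`,
#'   `variant_id` (gene lists), or a BED-style data frame with columns
#'   `chrom`, `start`, `end`, `name` (half-open 0-based intervals).
#' @return Named list of [region_genotypes]; regions with no surviving
#'   variants are skipped with a warning, single-variant regions are flagged
#'   (`single_variant = TRUE`).
#' @export
slice_regions <- function(data, region_spec) {
  region <- data$genotypes
  if (all(c("region_id", "variant_id") %in% names(region_spec))) {
    split_ids <- split(region_spec$variant_id, region_spec$region_id)
    idx_list <- lapply(split_ids, function(v)
      which(region$variant_ids %in% v))
  } else if (all(c("chrom", "start", "end") %in% names(region_spec))) {
    nm <- if ("name" %in% names(region_spec)) region_spec$name
          else paste0(region_spec$chrom, ":", region_spec$start, "-",
                      region_spec$end)
    idx_list <- lapply(seq_len(nrow(region_spec)), function(i)
      which(region$chrom == region_spec$chrom[i] &
              region$positions > region_spec$start[i] &
              region$positions <= region_spec$end[i]))
    names(idx_list) <- nm
  } else {
    stop("region_spec must have (region_id, variant_id) or (chrom, start, end)")
  }
  out <- list()
  for (nm in names(idx_list)) {
    idx <- idx_list[[nm]]
    if (!length(idx)) {
      warning("region '", nm, "' contains no surviving variants; skipped")
      next
    }
    r <- subset_region(region, idx)
    r$region_id <- nm
    out[[nm]] <- r
  }
  out
}
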