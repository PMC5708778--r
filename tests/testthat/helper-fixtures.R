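# Shared fixtures, built in code at test time.

# Write a small VCF file; `gts` is a character matrix (variants x samples)
# of GT strings such as "0/1". Returns the path.
write_tiny_vcf <- function(gts, ref = NULL, alt = NULL, chrom = "1",
                           pos = NULL, ids = NULL,
                           path = withr::local_tempfile(fileext = ".vcf",
                                                        .local_envir = parent.frame())) {
  L <- nrow(gts); n <- ncol(gts)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  if (is.null(ids)) ids <- paste0("snp", seq_len(L))
  samples <- paste0("s", seq_len(n))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(L), function(i)
      paste(c(chrom, pos[i], ids[i], ref[i], alt[i], ".", "PASS", ".", "GT",
              gts[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  path
}

write_tiny_phen <- function(status, samples = paste0("s", seq_along(status)),
                            path = withr::local_tempfile(fileext = ".tsv",
                                                         .local_envir = parent.frame())) {
  write.table(data.frame(sample_id = samples, status = status), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small polymorphic region with known genotypes.
toy_region <- function(X, ...) region_genotypes(as.matrix(X), ...)

# Fast simulation scenario for tests.
tiny_scenario <- function(...) {
  args <- list(...)
  defaults <- list(rho = 0.2, n_causal = 8L, n_noise = 0L,
                   composition = "rare_plus_common", or_model = 1.5,
                   n_cases = 150L, n_controls = 151L)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

# Independent classical Lewontin |D'| oracle for a biallelic 2x2 haplotype
# table (direct |D / Dmax| with the textbook Dmax).
lewontin_dprime_oracle <- function(h) {
  pA <- sum(h[1, ]); qB <- sum(h[, 1])
  D <- h[1, 1] - pA * qB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - qB), (1 - pA) * qB)
          else       min(pA * qB, (1 - pA) * (1 - qB))
  abs(D / dmax)
}

# Random valid biallelic haplotype table (both loci polymorphic).
random_hap_table <- function() {
  repeat {
    h <- matrix(stats::rexp(4), 2, 2)
    h <- h / sum(h)
    if (all(rowSums(h) > 1e-3) && all(colSums(h) > 1e-3)) return(h)
  }
}
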