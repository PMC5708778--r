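#' Simulation scenario configuration
#'
#' Describes one case-control genotype simulation scenario: a region of
#' `n_causal + n_noise` variants whose haplotypes arise by dichotomising a
#' latent multivariate normal vector with AR(1) correlation `rho^|i-j|`,
#' target MAFs drawn from the scenario's composition, and disease status
#' from an additive logistic model on the causal minor-allele counts.
#'
#' @param rho latent AR(1) correlation in `[0, 1)` (0 = linkage equilibrium).
#' @param n_causal number of causal variants (default 8).
#' @param n_noise number of non-causal variants (0, 4, 8, 16, 32 in the
#'   study design).
#' @param composition `"rare_only"` (all target MAFs ~ U(0.001, 0.01)) or
#'   `"rare_plus_common"` (each variant rare with probability 0.5, otherwise
#'   common with MAF ~ U(0.01, 0.5)).
#' @param or_model length-1 (one direction: all causal variants share this
#'   OR) or length-2 (two directions: risk OR, protective OR) numeric.
#' @param n_risk number of causal variants taking `or_model[1]` in a
#'   two-direction model; default `ceiling(n_causal / 2)` (balanced split).
#' @param n_cases,n_controls sampled case/control counts (defaults 3000 and
#'   3001, the study design).
#' @param baseline_prob disease probability for an individual carrying no
#'   minor alleles at causal variants (default 0.05).
#' @param maf_rare_range,maf_common_range uniform ranges for rare and common
#'   target MAFs.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(rho = 0, n_causal = 8L, n_noise = 0L,
                            composition = c("rare_only", "rare_plus_common"),
                            or_model = 1.2, n_risk = NULL,
                            n_cases = 3000L, n_controls = 3001L,
                            baseline_prob = 0.05,
                            maf_rare_range = c(0.001, 0.01),
                            maf_common_range = c(0.01, 0.5)) {
  composition <- match.arg(composition)
  stopifnot(rho >= 0, rho < 1, n_causal >= 1, n_noise >= 0,
            all(or_model > 0), length(or_model) %in% 1:2,
            n_cases >= 1, n_controls >= 1,
            baseline_prob > 0, baseline_prob < 1)
  if (is.null(n_risk))
    n_risk <- if (length(or_model) == 2L) ceiling(n_causal / 2) else n_causal
  structure(list(rho = rho, n_causal = as.integer(n_causal),
                 n_noise = as.integer(n_noise), composition = composition,
                 or_model = or_model, n_risk = as.integer(n_risk),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 baseline_prob = baseline_prob,
                 maf_rare_range = maf_rare_range,
                 maf_common_range = maf_common_range),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  ors <- paste(x$or_model, collapse = "/")
  cat(sprintf(
    "scenario: rho=%.2g, %d causal + %d noise, %s, OR %s, %d cases / %d controls\n",
    x$rho, x$n_causal, x$n_noise, x$composition, ors, x$n_cases, x$n_controls))
  invisible(x)
}

#' Draw target minor-allele frequencies for a scenario
#'
#' @param config a [scenario_config].
#' @param n number of variants (default all variants in the region).
#' @return Numeric vector of target MAFs.
#' @export
draw_mafs <- function(config, n = config$n_causal + config$n_noise) {
  rr <- config$maf_rare_range; cr <- config$maf_common_range
  if (config$composition == "rare_only") {
    stats::runif(n, rr[1], rr[2])
  } else {
    rare <- stats::runif(n) < 0.5
    ifelse(rare, stats::runif(n, rr[1], rr[2]), stats::runif(n, cr[1], cr[2]))
  }
}

#' Simulate haplotypes from the latent AR(1) Gaussian model
#'
#' Each haplotype is a latent draw from `N(0, Sigma)` with
#' `Sigma[i, j] = rho^|i-j|`, dichotomised so that allele i equals 1 (the
#' minor allele) exactly when the latent component exceeds
#' `qnorm(1 - maf_i)`; the marginal minor-allele probability is therefore
#' `maf_i` while `rho` induces LD between nearby variants.
#'
#' @param n number of haplotypes.
#' @param mafs target MAF vector (length L).
#' @param rho latent AR(1) correlation.
#' @return `n x L` 0/1 matrix.
#' @export
simulate_haplotypes <- function(n, mafs, rho) {
  L <- length(mafs)
  Z <- matrix(stats::rnorm(n * L), n, L)
  if (rho != 0 && L > 1L) {
    R <- chol(stats::toeplitz(rho^(0:(L - 1L))))
    Z <- Z %*% R
  }
  thr <- matrix(stats::qnorm(1 - mafs), n, L, byrow = TRUE)
  (Z > thr) + 0L
}

#' Simulate unrelated individuals (genotypes + haplotype pairs)
#'
#' Combines two independent haplotypes per individual into a minor-allele
#' count genotype.
#'
#' @inheritParams simulate_haplotypes
#' @return List with `X` (`n x L` genotype matrix) and `H1`, `H2` (the two
#'   haplotype matrices, `X = H1 + H2`).
#' @export
simulate_individuals <- function(n, mafs, rho) {
  H1 <- simulate_haplotypes(n, mafs, rho)
  H2 <- simulate_haplotypes(n, mafs, rho)
  list(X = H1 + H2, H1 = H1, H2 = H2)
}

#' Disease status under the additive logistic model
#'
#' `P(D = 1 | X) = logistic(beta0 + sum_causal ln(OR_i) X_i)` with
#' `beta0 = logit(baseline_prob)`.
#'
#' @param X `n x L` genotype matrix.
#' @param or_true length-L vector of per-variant true ORs (1 for non-causal).
#' @param baseline_prob disease probability at zero minor alleles.
#' @return Integer 0/1 status vector.
#' @export
assign_disease <- function(X, or_true, baseline_prob = 0.05) {
  stopifnot(ncol(X) == length(or_true))
  eta <- stats::qlogis(baseline_prob) + as.numeric(X %*% log(or_true))
  stats::rbinom(nrow(X), 1L, stats::plogis(eta))
}

#' Sample a case-control dataset under a scenario
#'
#' Draws target MAFs, assigns causal variants to random positions along the
#' AR(1) chain, simulates individuals and retains them until exactly
#' `n_cases` cases and `n_controls` controls are collected (retrospective
#' rejection sampling). When every OR equals 1 the status is independent of
#' genotype, so exactly `n_cases + n_controls` individuals are drawn and
#' labels assigned by permutation — distributionally identical and faster.
#'
#' @param config a [scenario_config].
#' @param seed optional RNG seed.
#' @param max_draws cap on simulated individuals before giving up.
#' @return Object of class `simulated_dataset`: `region` (a
#'   [region_genotypes] with phased haplotypes, individuals ordered as
#'   drawn), `status`, `truth` (data frame: variant, causal, or_true,
#'   target_maf) and `config`.
#' @export
sample_case_control <- function(config, seed = NULL, max_draws = 5e6) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$n_causal + config$n_noise
  mafs <- draw_mafs(config)
  causal_pos <- sort(sample.int(L, config$n_causal))
  or_true <- rep(1, L)
  if (length(config$or_model) == 1L) {
    or_true[causal_pos] <- config$or_model
  } else {
    risk <- causal_pos[seq_len(config$n_risk)]
    prot <- setdiff(causal_pos, risk)
    or_true[risk] <- config$or_model[1]
    or_true[prot] <- config$or_model[2]
  }
  nc <- config$n_cases; nu <- config$n_controls
  if (all(or_true == 1)) {
    n <- nc + nu
    ind <- simulate_individuals(n, mafs, config$rho)
    status <- integer(n)
    status[sample.int(n, nc)] <- 1L
    Xacc <- ind$X; H1 <- ind$H1; H2 <- ind$H2
  } else {
    Xacc <- H1 <- H2 <- NULL
    status <- integer(0)
    got_ca <- 0L; got_co <- 0L; drawn <- 0L
    prev_est <- config$baseline_prob
    while (got_ca < nc || got_co < nu) {
      need_ca <- nc - got_ca; need_co <- nu - got_co
      batch <- ceiling(1.2 * max(need_ca / max(prev_est, 1e-4),
                                 need_co / max(1 - prev_est, 1e-4)))
      batch <- min(max(batch, 1000L), 2e5)
      drawn <- drawn + batch
      if (drawn > max_draws)
        stop("case/control quotas unreachable within max_draws")
      ind <- simulate_individuals(batch, mafs, config$rho)
      y <- assign_disease(ind$X, or_true, config$baseline_prob)
      prev_est <- max(mean(y), 1 / batch)
      take_ca <- which(y == 1L)[seq_len(min(need_ca, sum(y == 1L)))]
      take_co <- which(y == 0L)[seq_len(min(need_co, sum(y == 0L)))]
      take <- sort(c(take_ca, take_co))
      Xacc <- rbind(Xacc, ind$X[take, , drop = FALSE])
      H1 <- rbind(H1, ind$H1[take, , drop = FALSE])
      H2 <- rbind(H2, ind$H2[take, , drop = FALSE])
      status <- c(status, y[take])
      got_ca <- got_ca + length(take_ca); got_co <- got_co + length(take_co)
    }
  }
  n <- length(status)
  haps <- matrix(0L, nrow = L, ncol = 2L * n)
  haps[, seq(1L, 2L * n, by = 2L)] <- t(H1)
  haps[, seq(2L, 2L * n, by = 2L)] <- t(H2)
  region <- region_genotypes(t(Xacc), region_id = "sim",
                             variant_ids = sprintf("snp%02d", seq_len(L)),
                             haplotypes = haps)
  truth <- data.frame(variant = region$variant_ids,
                      causal = seq_len(L) %in% causal_pos,
                      or_true = or_true, target_maf = mafs,
                      stringsAsFactors = FALSE)
  structure(list(region = region, status = status, truth = truth,
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  print(x$config)
  cat(sprintf("dataset: %d variants x %d individuals (%d cases, %d controls)\n",
              nrow(x$region$X), ncol(x$region$X),
              sum(x$status == 1), sum(x$status == 0)))
  invisible(x)
}

#' Export a simulated dataset as VCF plus phenotype TSV
#'
#' Writes the genotypes as an unphased VCF 4.2 file and the phenotype as a
#' two-column TSV (`sample_id`, `status`), the sidecar format accepted by
#' [read_genotypes()], so the simulator can feed any external tool.
#'
#' @param dataset a `simulated_dataset`.
#' @param vcf_path,phen_path output paths.
#' @return Invisibly, `vcf_path`.
#' @export
sim_to_vcf <- function(dataset, vcf_path, phen_path) {
  write_region_vcf(dataset$region, vcf_path)
  samples <- paste0("s", seq_along(dataset$status))
  utils::write.table(
    data.frame(sample_id = samples, status = dataset$status),
    phen_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}
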