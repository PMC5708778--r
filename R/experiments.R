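#' Experiment grid definition
#'
#' A list of simulation scenarios crossed with a set of region tests, run
#' for a fixed number of replicates per cell at significance level `alpha`.
#'
#' @param scenarios list of [scenario_config] objects.
#' @param methods character subset of c("ntr", "cmc", "wss", "skat",
#'   "skat_o").
#' @param reps replicates per scenario (study design: 1000).
#' @param alpha nominal significance level (study design: 0.05).
#' @param n_perm permutations per replicate for permutation-based tests
#'   (study design: 1000).
#' @param seed master seed; per-replicate seeds are derived deterministically
#'   from it so any cell can be reproduced in isolation.
#' @return Object of class `experiment_grid`.
#' @export
experiment_grid <- function(scenarios, methods = "ntr", reps = 1000L,
                            alpha = 0.05, n_perm = 1000L, seed = 1L) {
  stopifnot(length(scenarios) >= 1, reps >= 1, alpha > 0, alpha < 1)
  methods <- match.arg(methods, c("ntr", "cmc", "wss", "skat", "skat_o"),
                       several.ok = TRUE)
  if (!all(vapply(scenarios, inherits, logical(1), "scenario_config")))
    stop("scenarios must be scenario_config objects")
  structure(list(scenarios = scenarios, methods = methods,
                 reps = as.integer(reps), alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "experiment_grid")
}

# Deterministic per-replicate seed below 2^31, independent across
# (scenario, replicate) cells for a fixed master seed.
derive_seed <- function(master, scenario_idx, rep_idx) {
  m <- 2147483629
  s <- (as.double(master) %% m)
  s <- (s * 1009 + scenario_idx * 499979) %% m
  s <- (s * 31 + rep_idx * 7919) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Run a power / type-I-error experiment grid
#'
#' For every scenario x method cell, simulates `reps` datasets (per-replicate
#' seeds derived from the master seed), applies each method, and reports the
#' rejection rate at `alpha` with its Monte-Carlo standard error
#' `sqrt(r (1 - r) / reps)`. A method failure on a replicate is recorded as
#' missing, not as a rejection. With `cache_dir` set, completed scenario
#' cells are written to and reloaded from per-cell TSV files, making long
#' grids resumable.
#'
#' @param grid an [experiment_grid].
#' @param cache_dir optional directory for per-cell result caching.
#' @param verbose print per-cell progress.
#' @return Data frame with one row per scenario x method: scenario
#'   descriptors, `method`, `reps`, `n_ok`, `rejections`, `rate`, `se`.
#' @export
run_grid <- function(grid, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (si in seq_along(grid$scenarios)) {
    cfg <- grid$scenarios[[si]]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("cell_s%03d.tsv", si)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      pmat <- as.matrix(utils::read.delim(cache_file, check.names = FALSE))
    } else {
      pmat <- matrix(NA_real_, grid$reps, length(grid$methods),
                     dimnames = list(NULL, grid$methods))
      for (ri in seq_len(grid$reps)) {
        sd_r <- derive_seed(grid$seed, si, ri)
        dat <- sample_case_control(cfg, seed = sd_r)
        for (me in grid$methods) {
          pmat[ri, me] <- tryCatch(
            suppressWarnings(replicate_pvalue(dat, me, grid$n_perm, sd_r)),
            error = function(e) NA_real_)
        }
      }
      if (!is.null(cache_file))
        utils::write.table(pmat, cache_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    for (me in grid$methods) {
      p <- pmat[, me]
      ok <- !is.na(p)
      rate <- mean(p[ok] < grid$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = si, rho = cfg$rho, n_causal = cfg$n_causal,
        n_noise = cfg$n_noise, composition = cfg$composition,
        or_model = paste(cfg$or_model, collapse = "/"),
        n_cases = cfg$n_cases, n_controls = cfg$n_controls,
        method = me, reps = grid$reps, n_ok = sum(ok),
        rejections = sum(p[ok] < grid$alpha), rate = rate,
        se = sqrt(rate * (1 - rate) / sum(ok)), stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("scenario %d/%d done", si, length(grid$scenarios)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

replicate_pvalue <- function(dat, method, n_perm, seed) {
  fit <- switch(method,
    ntr = ntr_region_test(dat$region, dat$status, n_perm = n_perm,
                          seed = seed + 1L),
    cmc = cmc_test(dat$region, dat$status),
    wss = wss_test(dat$region, dat$status, n_perm = n_perm, seed = seed + 2L),
    skat = skat_test(dat$region, dat$status),
    skat_o = skat_o_test(dat$region, dat$status),
    stop("unknown method ", method))
  fit$p
}

#' Summarise a grid result in figure-panel layout
#'
#' Groups the [run_grid()] table by (composition, or_model, rho, n_noise)
#' and spreads methods into columns, the layout used to compare methods
#' across correlation and noise conditions. Cells missing from the input
#' propagate as `NA`, not zero.
#'
#' @param table data frame from [run_grid()].
#' @param path optional TSV output path.
#' @return Wide data frame: one row per scenario, one `rate` column per
#'   method.
#' @export
summarize_grid <- function(table, path = NULL) {
  key_cols <- c("composition", "or_model", "rho", "n_noise",
                "n_cases", "n_controls")
  keys <- unique(table[key_cols])
  methods <- unique(table$method)
  out <- keys
  for (me in methods) {
    sub <- table[table$method == me, , drop = FALSE]
    idx <- match(do.call(paste, keys), do.call(paste, sub[key_cols]))
    out[[paste0("rate_", me)]] <- sub$rate[idx]
    out[[paste0("se_", me)]] <- sub$se[idx]
  }
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Build the standard one-direction / two-direction scenario lists
#'
#' Convenience constructor for the study's scenario grids: crossings of
#' `rho` in \{0, 0.2, 0.4, 0.6\}, noise counts \{0, 4, 8, 16, 32\}, the two
#' compositions and the OR models.
#'
#' @param rho,n_noise,composition vectors to cross.
#' @param or_models list of OR models (length-1 = one direction, length-2 =
#'   two directions); `list(1)` gives the null grid.
#' @param ... passed to [scenario_config()] (e.g. reduced `n_cases`).
#' @return List of [scenario_config] objects.
#' @export
standard_scenarios <- function(rho = c(0, 0.2, 0.4, 0.6),
                               n_noise = c(0, 4, 8, 16, 32),
                               composition = c("rare_only",
                                               "rare_plus_common"),
                               or_models = list(1.2, 1.5),
                               ...) {
  out <- list()
  for (co in composition) for (om in or_models) for (r in rho)
    for (nn in n_noise)
      out[[length(out) + 1L]] <- scenario_config(
        rho = r, n_noise = nn, composition = co, or_model = om, ...)
  out
}
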