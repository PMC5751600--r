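#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline with validated defaults.
#' The configuration (including the RNG seed) is embedded as a comment header
#' in every TSV artifact so a run can be reproduced from its outputs alone.
#'
#' @param alpha differential-expression p-value cutoff.
#' @param use_fdr if `TRUE`, apply Benjamini-Hochberg adjustment before the
#'   `alpha` cutoff instead of using raw p-values.
#' @param sample_cut_height height at which the average-linkage sample tree
#'   (Euclidean distances) is cut when trimming outlier samples.
#' @param dispersion_mult flag samples whose mean deviates from the grand mean
#'   by more than this multiple of the SD of per-sample means.
#' @param powers candidate soft-thresholding powers.
#' @param rsq_target scale-free topology fit target; the smallest power
#'   reaching it is chosen.
#' @param min_module_size clusters smaller than this are relabelled "grey".
#' @param cut_height static cut height on the TOM-dissimilarity dendrogram.
#' @param ppi_threshold minimum PPI confidence kept in module networks
#'   (proxy for a "3-star or above" interaction grade).
#' @param k_const empirical constant of the node-weight and RP-score formulas.
#' @param log_base base of the logarithm in the module enrichment score.
#' @param top_fraction fraction of ranked drugs flagged as candidates.
#' @param seed integer RNG seed recorded in every output header.
#'
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(alpha = 0.05,
                       use_fdr = FALSE,
                       sample_cut_height = 100,
                       dispersion_mult = 3,
                       powers = 1:20,
                       rsq_target = 0.8,
                       min_module_size = 30,
                       cut_height = 0.97,
                       ppi_threshold = 0.75,
                       k_const = 2,
                       log_base = 10,
                       top_fraction = 0.01,
                       seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1)
  stopifnot(isTRUE(use_fdr) || isFALSE(use_fdr))
  stopifnot(is.numeric(sample_cut_height), sample_cut_height > 0)
  stopifnot(is.numeric(dispersion_mult), dispersion_mult > 0)
  stopifnot(is.numeric(powers), length(powers) >= 1, all(powers > 0))
  stopifnot(is.numeric(rsq_target), rsq_target > 0, rsq_target <= 1)
  stopifnot(is.numeric(min_module_size), min_module_size >= 1)
  stopifnot(is.numeric(cut_height), cut_height > 0)
  stopifnot(is.numeric(ppi_threshold), ppi_threshold >= 0, ppi_threshold <= 1)
  stopifnot(is.numeric(k_const), k_const > 0)
  stopifnot(is.numeric(log_base), log_base > 1)
  stopifnot(is.numeric(top_fraction), top_fraction > 0, top_fraction <= 1)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  cfg <- list(alpha = alpha, use_fdr = use_fdr,
              sample_cut_height = sample_cut_height,
              dispersion_mult = dispersion_mult,
              powers = as.integer(powers), rsq_target = rsq_target,
              min_module_size = as.integer(min_module_size),
              cut_height = cut_height, ppi_threshold = ppi_threshold,
              k_const = k_const, log_base = log_base,
              top_fraction = top_fraction, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("modrepo run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}

# One "# key=value" comment line per setting; prepended to every TSV artifact.
config_header <- function(config) {
  if (is.null(config)) return(character(0))
  stopifnot(inherits(config, "run_config"))
  c("# modrepo run_config",
    vapply(names(config), function(nm) {
      sprintf("# %s=%s", nm, paste(config[[nm]], collapse = ","))
    }, character(1)))
}
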