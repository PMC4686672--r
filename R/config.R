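#' Pipeline configuration
#'
#' Collects every tunable threshold of the screen in one validated object so
#' that all stage defaults have a single provenance point. Values can be
#' overridden individually, or loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param alpha_fdr Significance level applied to FDR-adjusted p-values
#'   (differential expression, pathway enrichment). Default 0.05.
#' @param mc_iterations Number of Monte Carlo iterations for the set-overlap
#'   test. Default 1000.
#' @param mc_quantile Null-distribution quantile above which an observed
#'   overlap is called significant. Default 0.95.
#' @param fuzziness_m Fuzzy c-means membership exponent (must exceed 1).
#'   Default 2.
#' @param c_range Candidate cluster numbers for the validity-index vote.
#'   Default `2:12`.
#' @param motif_p_threshold Per-site p-value cutoff for PSSM hits.
#'   Default 1e-4.
#' @param promoter_length Scanned upstream promoter length in bp.
#'   Default 1000.
#' @param rng_seed Integer seed threaded through stochastic stages.
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(alpha_fdr = 0.01)
#' cfg$mc_iterations
pipeline_config <- function(alpha_fdr = 0.05,
                            mc_iterations = 1000L,
                            mc_quantile = 0.95,
                            fuzziness_m = 2,
                            c_range = 2:12,
                            motif_p_threshold = 1e-4,
                            promoter_length = 1000L,
                            rng_seed = 1L) {
  cfg <- list(
    alpha_fdr = as.numeric(alpha_fdr),
    mc_iterations = as.integer(mc_iterations),
    mc_quantile = as.numeric(mc_quantile),
    fuzziness_m = as.numeric(fuzziness_m),
    c_range = as.integer(c_range),
    motif_p_threshold = as.numeric(motif_p_threshold),
    promoter_length = as.integer(promoter_length),
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!(cfg$alpha_fdr > 0 && cfg$alpha_fdr < 1))
    abort("`alpha_fdr` must lie strictly between 0 and 1.")
  if (cfg$mc_iterations < 1L)
    abort("`mc_iterations` must be at least 1.")
  if (!(cfg$mc_quantile > 0 && cfg$mc_quantile < 1))
    abort("`mc_quantile` must lie strictly between 0 and 1.")
  if (!(cfg$fuzziness_m > 1))
    abort("`fuzziness_m` must be greater than 1.")
  if (cfg$promoter_length < 1L)
    abort("`promoter_length` must be at least 1 bp.")
  if (!(cfg$motif_p_threshold > 0 && cfg$motif_p_threshold < 1))
    abort("`motif_p_threshold` must lie strictly between 0 and 1.")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path of the YAML configuration.
#' @return For `read_pipeline_config`, a `pipeline_config` object; unknown
#'   keys raise an error so typos do not silently fall back to defaults.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    abort(paste0("Unknown configuration keys: ", paste(extra, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` object.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  alpha_fdr:         %g\n", x$alpha_fdr))
  cat(sprintf("  mc_iterations:     %d\n", x$mc_iterations))
  cat(sprintf("  mc_quantile:       %g\n", x$mc_quantile))
  cat(sprintf("  fuzziness_m:       %g\n", x$fuzziness_m))
  cat(sprintf("  c_range:           %s\n", paste(range(x$c_range), collapse = "-")))
  cat(sprintf("  motif_p_threshold: %g\n", x$motif_p_threshold))
  cat(sprintf("  promoter_length:   %d bp\n", x$promoter_length))
  cat(sprintf("  rng_seed:          %d\n", x$rng_seed))
  invisible(x)
}
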