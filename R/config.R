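#' Analysis configuration
#'
#' Single source of the tunable parameters of the analysis. Defaults encode
#' the screen's published rule: the 150 siRNAs with the strongest reduction
#' are selected, and a gene is a hit when at least 2 of its 3 siRNAs are
#' among them.
#'
#' @param top_k number of top-ranked siRNAs selected (k, default 150).
#' @param min_concordant minimum number of a gene's siRNAs required in the
#'   top k for a hit call (m, default 2).
#' @param sirnas_per_gene siRNAs per gene in the library (r, default 3).
#' @param viability_z_threshold robust-z threshold c on the density channel:
#'   an siRNA with `|z_mb| >= c` is flagged as a viability confound and
#'   removed from hit candidacy (default 2; `Inf` disables the filter and
#'   reproduces ratio-only behavior).
#' @param normalization_method `"plate_median"` (default) or
#'   `"percent_of_neg_controls"` (control-percentage QC normalization).
#' @param score_on_log_ratio score on log2 of the normalized ratio (default
#'   `TRUE`) so reductions and increases are symmetric.
#' @param direction effect direction scored positive: `"reduction"` (default)
#'   or `"increase"` (for negative regulators).
#' @param mad_consistency_constant kappa in `kappa * MAD` (default 1.4826).
#' @param mb_floor validity floor on normalized density (default 0.1): wells
#'   with under 10% of plate-typical density are excluded.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(top_k = 150, min_concordant = 2, sirnas_per_gene = 3,
                          viability_z_threshold = 2.0,
                          normalization_method = c("plate_median",
                                                   "percent_of_neg_controls"),
                          score_on_log_ratio = TRUE,
                          direction = c("reduction", "increase"),
                          mad_consistency_constant = 1.4826,
                          mb_floor = 0.1) {
  normalization_method <- match.arg(normalization_method)
  direction <- match.arg(direction)
  if (min_concordant < 1 || min_concordant > sirnas_per_gene)
    stop_argument("need 0 < min_concordant <= sirnas_per_gene")
  if (top_k < min_concordant)
    stop_argument("need top_k >= min_concordant")
  if (viability_z_threshold <= 0)
    stop_argument("viability_z_threshold must be > 0")
  structure(list(top_k = as.integer(top_k),
                 min_concordant = as.integer(min_concordant),
                 sirnas_per_gene = as.integer(sirnas_per_gene),
                 viability_z_threshold = viability_z_threshold,
                 normalization_method = normalization_method,
                 score_on_log_ratio = isTRUE(score_on_log_ratio),
                 direction = direction,
                 mad_consistency_constant = mad_consistency_constant,
                 mb_floor = mb_floor),
            class = "screen_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file; keys are the arguments of [screen_config()]
#'   (unknown keys are an error).
#' @param config a `screen_config` (for writing).
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(screen_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_format("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$viability_z_threshold) &&
      identical(raw$viability_z_threshold, ".inf"))
    raw$viability_z_threshold <- Inf
  do.call(screen_config, raw)
}

#' @rdname read_screen_config
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
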