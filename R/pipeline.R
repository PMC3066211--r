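#' Control-percentage scatter table
#'
#' The data behind the control QC scatter plot: for every replicate and
#' plate, both channels are expressed as percentages of the plate's
#' negative-control mean (set at 100%), one row per well. Negative controls
#' cluster at (100, 100) in expectation; positive controls retain density
#' but lose reporter activity.
#'
#' @param screen a [screen_dataset()] of raw readouts.
#' @param layout a [plate_layout()].
#' @param library an [sirna_library()].
#' @return data.frame with columns `replicate`, `plate`, `well`, `role`,
#'   `mb_percent`, `erod_percent`.
#' @export
control_scatter_export <- function(screen, layout, library) {
  ew <- effective_wells(layout, library)
  ew <- ew[ew$role != "empty", , drop = FALSE]
  v <- screen$values
  idx <- match(paste(v$plate, v$well), paste(ew$plate, ew$well))
  v <- v[!is.na(idx), , drop = FALSE]
  v$role <- ew$role[idx[!is.na(idx)]]
  out <- NULL
  for (grp in split(v, list(v$replicate, v$plate), drop = TRUE)) {
    role_vec <- stats::setNames(grp$role[!duplicated(grp$well)],
                                grp$well[!duplicated(grp$well)])
    plate_id <- sprintf("%d (replicate %d)", grp$plate[1L], grp$replicate[1L])
    e <- grp[grp$channel == "EROD", ]
    m <- grp[grp$channel == "MB", ]
    pe <- percent_of_neg_controls(stats::setNames(e$value, e$well), role_vec,
                                  plate_id)
    pm <- percent_of_neg_controls(stats::setNames(m$value, m$well), role_vec,
                                  plate_id)
    wells <- union(names(pe), names(pm))
    out <- rbind(out, data.frame(
      replicate = grp$replicate[1L], plate = grp$plate[1L], well = wells,
      role = unname(role_vec[wells]),
      mb_percent = unname(pm[wells]), erod_percent = unname(pe[wells]),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Run the full screen analysis pipeline
#'
#' Orchestrates the whole analysis from files (or in-memory objects) to
#' result tables on disk: read -> validate -> normalize -> ratio -> robust z
#' -> summarize -> viability filter -> rank -> gene hit calling ->
#' term enrichment (when an annotation is given) -> single-channel density
#' analysis. All result tables are written as TSV with numeric columns at 6
#' significant digits; re-running with the same inputs gives byte-identical
#' outputs.
#'
#' @param readouts path to a readout file, or a [screen_dataset()].
#' @param layout path to a layout table, or a [plate_layout()].
#' @param library path to an siRNA library table, or an [sirna_library()].
#' @param annotation optional path to a GMT file, or an [annotation_set()];
#'   when absent the enrichment stage is skipped and the report notes it.
#' @param config path to a YAML configuration, or a [screen_config()].
#' @param out_dir output directory (created if needed).
#' @return A list of class `run_report`: `config` echo, `validation`
#'   summary, `correlations`, `control_separation` (per plate/replicate mean
#'   normalized positive- over negative-control reporter ratio),
#'   `exclusions`, `n_hits`, `hit_rate_percent`, `enrichment_skipped` and the
#'   output-file `manifest`.
#' @export
run_pipeline <- function(readouts, layout, library, annotation = NULL,
                         config = screen_config(), out_dir) {
  if (is.character(config)) config <- read_screen_config(config)
  if (is.character(layout)) layout <- read_layout(layout)
  if (is.character(library)) library <- read_sirna_library(library)
  if (is.character(readouts)) readouts <- read_readouts(readouts, layout, library)
  if (is.character(annotation)) annotation <- read_gmt(annotation)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  validation <- validate_screen(readouts, layout, library)
  if (nrow(validation$incomplete_genes) > 0L)
    warning("library genes with unexpected siRNA counts; see validation report")

  scored <- score_screen(readouts, layout, library, config)
  hits <- call_gene_hits(scored, config)
  density <- density_hit_analysis(scored, config)

  enr <- NULL
  if (!is.null(annotation))
    enr <- enrich_hits(hit_genes(hits), annotation)

  # control separation: mean normalized pos-control reporter level relative
  # to the neg-control mean, per replicate and plate
  w <- scored$wells
  sep <- do.call(rbind, lapply(split(w, list(w$replicate, w$plate),
                                     drop = TRUE), function(p) {
    neg <- p$norm_erod[p$role == "neg_control"]
    pos <- p$norm_erod[p$role == "pos_control"]
    data.frame(replicate = p$replicate[1L], plate = p$plate[1L],
               neg_mean = mean(neg, na.rm = TRUE),
               pos_mean = mean(pos, na.rm = TRUE),
               pos_over_neg = mean(pos, na.rm = TRUE) / mean(neg, na.rm = TRUE))
  }))
  rownames(sep) <- NULL
  sep <- sep[order(sep$replicate, sep$plate), , drop = FALSE]

  scatter <- control_scatter_export(readouts, layout, library)

  files <- list(
    wells = file.path(out_dir, "normalized_wells.tsv"),
    sirna_scores = file.path(out_dir, "sirna_scores.tsv"),
    hits_erod = file.path(out_dir, "hits_erod.tsv"),
    hits_density = file.path(out_dir, "hits_density.tsv"),
    qc_correlations = file.path(out_dir, "qc_replicate_correlations.tsv"),
    control_separation = file.path(out_dir, "qc_control_separation.tsv"),
    control_scatter = file.path(out_dir, "control_scatter.tsv"))
  write_tsv(scored$wells, files$wells, digits = 6)
  write_tsv(scored$sirnas, files$sirna_scores, digits = 6)
  write_tsv(as.data.frame(hits), files$hits_erod, digits = 6)
  write_tsv(as.data.frame(density), files$hits_density, digits = 6)
  cm <- as.data.frame(scored$correlations)
  cm <- cbind(replicate = rownames(scored$correlations), cm)
  write_tsv(cm, files$qc_correlations, digits = 6)
  write_tsv(sep, files$control_separation, digits = 6)
  write_tsv(scatter, files$control_scatter, digits = 6)
  if (!is.null(enr)) {
    files$enrichment <- file.path(out_dir, "enrichment.tsv")
    write_tsv(as.data.frame(enr), files$enrichment, digits = 6)
  }

  manifest <- data.frame(name = names(files),
                         path = unlist(files, use.names = FALSE),
                         exists = file.exists(unlist(files, use.names = FALSE)),
                         size = file.size(unlist(files, use.names = FALSE)),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL

  structure(list(config = config,
                 validation = validation,
                 correlations = scored$correlations,
                 control_separation = sep,
                 exclusions = scored$exclusions,
                 n_hits = attr(hits, "n_hits"),
                 hit_rate_percent = attr(hits, "hit_rate_percent"),
                 enrichment_skipped = is.null(annotation),
                 hits = hits, density_hits = density, enrichment = enr,
                 scored = scored, manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  validation: %s\n",
              if (x$validation$complete) "complete" else "issues found"))
  if (ncol(x$correlations) > 1L)
    cat(sprintf("  replicate correlations: %s\n",
                paste(sprintf("%.2f", x$correlations[upper.tri(x$correlations)]),
                      collapse = ", ")))
  cat(sprintf("  mean control separation (pos/neg reporter): %.3f\n",
              mean(x$control_separation$pos_over_neg)))
  if (length(x$exclusions))
    cat(sprintf("  exclusions: %s\n",
                paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
                      collapse = ", ")))
  cat(sprintf("  hits: %d gene(s), %d%% of genes\n", x$n_hits,
              x$hit_rate_percent))
  if (x$enrichment_skipped)
    cat("  enrichment: skipped (no annotation supplied)\n")
  else
    cat(sprintf("  enrichment: %d enriched term(s)\n", nrow(x$enrichment)))
  cat(sprintf("  outputs: %d file(s) in place\n", sum(x$manifest$exists)))
  invisible(x)
}
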