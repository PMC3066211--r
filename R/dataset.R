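#' Screen dataset: per-well two-channel readouts
#'
#' A `screen_dataset` holds the raw (or normalized) per-well values of a
#' screen: one row per (replicate, plate, well, channel). The two channels are
#' `"EROD"` (reporter activity, the slope of a kinetic fluorescence read in
#' fluorescence units per minute) and `"MB"` (methylene blue absorbance, a
#' cell-density proxy). Kinetic fluorescence traces, when present, are kept
#' alongside the values they were reduced to.
#'
#' @param values data.frame with columns `replicate`, `plate`, `well`,
#'   `channel`, `value`; values must be non-negative (or `NA` for explicitly
#'   missing wells).
#' @param traces optional named list of kinetic traces, keyed
#'   `"replicate/plate/well"`, each a data.frame with columns `time` (minutes)
#'   and `fluorescence`.
#' @return An object of class `screen_dataset`.
#' @export
screen_dataset <- function(values, traces = NULL) {
  need <- c("replicate", "plate", "well", "channel", "value")
  miss <- setdiff(need, names(values))
  if (length(miss))
    stop_format("readout table lacks column(s): %s", paste(miss, collapse = ", "))
  values <- as.data.frame(values)[need]
  values$replicate <- as.integer(values$replicate)
  values$plate <- as.integer(values$plate)
  values$value <- as.numeric(values$value)
  bad <- !is.na(values$value) & values$value < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_validation("negative readout at replicate %d, plate %d, well %s",
                    values$replicate[i], values$plate[i], values$well[i])
  }
  if (!all(values$channel %in% c("EROD", "MB")))
    stop_format("unknown channel(s): %s",
                paste(setdiff(unique(values$channel), c("EROD", "MB")),
                      collapse = ", "))
  key <- paste(values$replicate, values$plate, values$well, values$channel)
  if (anyDuplicated(key))
    stop_validation("duplicate readout row(s): %s",
                    paste(utils::head(unique(key[duplicated(key)]), 3),
                          collapse = "; "))
  structure(list(values = values,
                 n_replicates = length(unique(values$replicate)),
                 traces = traces),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  v <- x$values
  cat(sprintf("<screen_dataset> %d replicates, %d plates, %d well-values%s\n",
              x$n_replicates, length(unique(v$plate)), nrow(v),
              if (is.null(x$traces)) "" else
                sprintf(", %d kinetic traces", length(x$traces))))
  invisible(x)
}

#' Read per-well readouts, reducing kinetic traces to activities
#'
#' Reads a delimited readout file with header columns `experiment`, `plate`,
#' `well`, `channel`, `value`. Kinetic rows instead carry `time` and
#' `fluorescence`; all kinetic rows of one (experiment, plate, well) form a
#' trace which is reduced to an EROD activity by [erod_slope()] (the trace is
#' retained in the returned object). Wells are checked against the plate
#' layout and values must be non-negative.
#'
#' @param path readout file.
#' @param layout a [plate_layout()].
#' @param library an [sirna_library()] (used only for bound checks here;
#'   see [validate_screen()] for completeness reporting).
#' @return A [screen_dataset()].
#' @export
read_readouts <- function(path, layout, library) {
  df <- read_delimited(path, c("experiment", "plate", "well", "channel"))
  kinetic_cols <- all(c("time", "fluorescence") %in% names(df))
  if (!kinetic_cols && !"value" %in% names(df))
    stop_format("%s: missing required column(s): value", basename(path))
  bad_well <- setdiff(unique(df$well), names(roles(layout)))
  if (length(bad_well))
    stop_validation("well(s) not in layout: %s",
                    paste(utils::head(bad_well, 5), collapse = ", "))

  traces <- NULL
  if (kinetic_cols) {
    is_kin <- !is.na(df$time) & !is.na(df$fluorescence)
  } else {
    is_kin <- rep(FALSE, nrow(df))
  }
  vals <- df[!is_kin, , drop = FALSE]
  if (!"value" %in% names(vals)) vals$value <- NA_real_
  if (any(is_kin)) {
    kin <- df[is_kin, , drop = FALSE]
    keys <- paste(kin$experiment, kin$plate, kin$well, sep = "/")
    traces <- lapply(split(kin[c("time", "fluorescence")], keys), function(tr)
      tr[order(tr$time), , drop = FALSE])
    slopes <- vapply(traces, function(tr)
      erod_slope(tr), numeric(1))
    kv <- data.frame(do.call(rbind, strsplit(names(traces), "/", fixed = TRUE)),
                     stringsAsFactors = FALSE)
    names(kv) <- c("experiment", "plate", "well")
    kv$channel <- "EROD"
    kv$value <- unname(slopes)
    keep <- intersect(c("experiment", "plate", "well", "channel", "value"),
                      names(vals))
    vals <- rbind(vals[keep], kv[keep])
  }
  names(vals)[names(vals) == "experiment"] <- "replicate"
  screen_dataset(vals, traces = traces)
}

#' Write per-well readouts
#'
#' Inverse of [read_readouts()]: writes a TSV with columns `experiment`,
#' `plate`, `well`, `channel`, `value` at full float precision, so that a
#' write/read round trip reproduces every value bit-exactly. When the dataset
#' carries kinetic traces these are written as kinetic rows (`time`,
#' `fluorescence`) in place of the EROD value rows they were reduced from.
#'
#' @param screen a [screen_dataset()].
#' @param path output file.
#' @export
write_readouts <- function(screen, path) {
  stopifnot(inherits(screen, "screen_dataset"))
  v <- screen$values
  out <- data.frame(experiment = v$replicate, plate = v$plate, well = v$well,
                    channel = v$channel, value = v$value)
  if (!is.null(screen$traces)) {
    out <- out[out$channel != "EROD", , drop = FALSE]
    out$time <- NA_real_
    out$fluorescence <- NA_real_
    kin <- do.call(rbind, lapply(names(screen$traces), function(k) {
      parts <- strsplit(k, "/", fixed = TRUE)[[1L]]
      tr <- screen$traces[[k]]
      data.frame(experiment = as.integer(parts[1L]),
                 plate = as.integer(parts[2L]), well = parts[3L],
                 channel = "EROD", value = NA_real_,
                 time = tr$time, fluorescence = tr$fluorescence)
    }))
    out <- rbind(out, kin)
  }
  write_tsv(out, path)
}

#' Validate a screen against its layout and library
#'
#' Report-only completeness check: lists (replicate, plate, well, channel)
#' combinations expected from the layout/library but absent from the data,
#' siRNAs in the library that were never measured, and genes whose number of
#' library siRNAs differs from `sirnas_per_gene`. The report is empty exactly
#' when the screen is complete.
#'
#' @param screen a [screen_dataset()].
#' @param layout a [plate_layout()].
#' @param library an [sirna_library()].
#' @return A list of class `screen_validation` with elements `missing`
#'   (data.frame), `orphan_sirnas` (character), `incomplete_genes`
#'   (data.frame) and `complete` (logical).
#' @export
validate_screen <- function(screen, layout, library) {
  stopifnot(inherits(screen, "screen_dataset"))
  ew <- effective_wells(layout, library)
  ew <- ew[ew$role != "empty", , drop = FALSE]
  reps <- sort(unique(screen$values$replicate))
  exp_grid <- expand.grid(idx = seq_len(nrow(ew)), replicate = reps,
                          channel = c("EROD", "MB"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- data.frame(replicate = exp_grid$replicate,
                         plate = ew$plate[exp_grid$idx],
                         well = ew$well[exp_grid$idx],
                         channel = exp_grid$channel,
                         stringsAsFactors = FALSE)
  have <- screen$values[!is.na(screen$values$value), ]
  hk <- paste(have$replicate, have$plate, have$well, have$channel)
  ek <- paste(expected$replicate, expected$plate, expected$well, expected$channel)
  missing <- expected[!(ek %in% hk), , drop = FALSE]
  rownames(missing) <- NULL

  measured <- unique(paste(have$plate, have$well))
  lk <- paste(library$plate, library$well)
  orphans <- library$sirna_id[!(lk %in% measured)]

  r <- attr(library, "sirnas_per_gene")
  n <- table(library$gene)
  bad <- names(n)[n != r]
  incomplete <- data.frame(gene = bad,
                           n_sirnas = as.integer(n[bad]),
                           expected = rep(r, length(bad)),
                           stringsAsFactors = FALSE)
  rownames(incomplete) <- NULL

  structure(list(missing = missing, orphan_sirnas = orphans,
                 incomplete_genes = incomplete,
                 complete = nrow(missing) == 0L && length(orphans) == 0L &&
                   nrow(incomplete) == 0L),
            class = "screen_validation")
}

#' @export
print.screen_validation <- function(x, ...) {
  if (x$complete) {
    cat("<screen_validation> complete: no issues found\n")
  } else {
    cat("<screen_validation>\n")
    cat(sprintf("  missing well-values: %d\n", nrow(x$missing)))
    if (nrow(x$missing)) print(utils::head(x$missing))
    cat(sprintf("  orphan siRNAs (never measured): %d\n",
                length(x$orphan_sirnas)))
    cat(sprintf("  genes with wrong siRNA count: %d\n",
                nrow(x$incomplete_genes)))
    if (nrow(x$incomplete_genes)) print(x$incomplete_genes)
  }
  invisible(x)
}
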