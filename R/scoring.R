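#' Reduce a kinetic fluorescence trace to an EROD activity
#'
#' EROD activity is read kinetically: resorufin fluorescence is followed over
#' a 15-minute window and the activity is the ordinary least-squares slope of
#' fluorescence against time, in fluorescence units per minute. All points in
#' the window are used, unweighted.
#'
#' @param trace a data.frame or matrix whose first two columns are time
#'   (minutes) and fluorescence, or a list with elements `time` and
#'   `fluorescence`.
#' @return The OLS slope (fluorescence/min).
#' @examples
#' erod_slope(data.frame(time = c(0, 5, 10, 15),
#'                       fluorescence = c(100, 150, 200, 250)))  # 10
#' @export
erod_slope <- function(trace) {
  if (is.list(trace) && !is.data.frame(trace) &&
      all(c("time", "fluorescence") %in% names(trace))) {
    t <- as.numeric(trace$time); y <- as.numeric(trace$fluorescence)
  } else {
    trace <- as.data.frame(trace)
    if (all(c("time", "fluorescence") %in% names(trace))) {
      t <- as.numeric(trace$time); y <- as.numeric(trace$fluorescence)
    } else {
      t <- as.numeric(trace[[1L]]); y <- as.numeric(trace[[2L]])
    }
  }
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L || length(unique(t)) < 2L)
    stop_degenerate_trace("kinetic trace needs >= 2 distinct time points (got %d)",
                          length(unique(t)))
  tc <- t - mean(t)
  sum(tc * y) / sum(tc * tc)
}

#' Express plate values as percentages of the negative controls
#'
#' Control-percentage normalization for QC plots: each well value is divided
#' by the mean of the plate's negative-control wells and multiplied by 100,
#' so the control mean sits at 100%.
#'
#' @param values named numeric vector of one plate's values (names are well
#'   addresses); `NA` marks missing wells.
#' @param layout a [plate_layout()] or a named role vector as from [roles()].
#' @param plate plate identifier, used only in error messages.
#' @return Named numeric vector of percentages (same names as `values`).
#' @examples
#' lay <- plate_layout()
#' v <- setNames(rep(100, 96), all_wells(lay))
#' v["A1"] <- 55
#' percent_of_neg_controls(v, lay)[["A1"]]  # 55
#' @export
percent_of_neg_controls <- function(values, layout, plate = NA) {
  role <- if (inherits(layout, "plate_layout")) roles(layout) else layout
  neg <- values[names(values) %in% names(role)[role == "neg_control"]]
  neg <- neg[!is.na(neg)]
  if (length(neg) == 0L)
    stop_normalize("plate %s: no non-missing negative-control well", plate)
  m <- mean(neg)
  if (m <= 0)
    stop_normalize("plate %s: negative-control mean is %g (must be > 0)",
                   plate, m)
  100 * values / m
}

#' Normalize plate values by the sample-well median
#'
#' Per-plate, per-channel normalization: every well (samples and controls
#' alike) is divided by the median of the plate's non-missing sample wells,
#' which removes multiplicative plate effects. The sample-well median of the
#' output is 1 by construction.
#'
#' @inheritParams percent_of_neg_controls
#' @return Named numeric vector of normalized values.
#' @export
plate_median_normalize <- function(values, layout, plate = NA) {
  role <- if (inherits(layout, "plate_layout")) roles(layout) else layout
  smp <- values[names(values) %in% names(role)[role == "sample"]]
  smp <- smp[!is.na(smp)]
  if (length(smp) < 3L)
    stop_normalize("plate %s: fewer than 3 non-missing sample wells", plate)
  med <- stats::median(smp)
  if (med <= 0)
    stop_normalize("plate %s: sample-well median is %g (must be > 0)",
                   plate, med)
  values / med
}

#' Activity/density ratio with a viability validity floor
#'
#' The per-well ratio of normalized reporter activity to normalized cell
#' density. A well whose normalized density falls below `mb_floor` has too
#' few cells for the activity reading to be interpretable; instead of an
#' explosive ratio the well is excluded, and the exclusion is a value, not an
#' error.
#'
#' @param norm_erod,norm_mb normalized channel values (same plate).
#' @param mb_floor validity floor on normalized density (default 0.1).
#' @return A list with elements `ratio` (numeric, `NA` where excluded) and
#'   `excluded` (character reason, `NA` where kept). Vectorized.
#' @examples
#' channel_ratio(2, 1, 0.1)$ratio        # 2
#' channel_ratio(0.5, 0.01, 0.1)$excluded  # "low_viability_signal"
#' @export
channel_ratio <- function(norm_erod, norm_mb, mb_floor = 0.1) {
  low <- !is.na(norm_mb) & norm_mb < mb_floor
  ratio <- ifelse(low, NA_real_, norm_erod / norm_mb)
  excluded <- ifelse(low, "low_viability_signal", NA_character_)
  list(ratio = ratio, excluded = excluded)
}

#' Robust z-score against a reference sample
#'
#' `z = (median(sample) - x) / (kappa * MAD(sample))` with the reduction-
#' positive sign convention: a value below the sample median (a knockdown
#' that reduces the readout) gets a positive z. `direction = "increase"`
#' negates the score for screens after effects that raise the readout.
#'
#' @param sample numeric reference sample (>= 3 values, MAD > 0).
#' @param x value(s) to score.
#' @param direction `"reduction"` (default) or `"increase"`.
#' @param kappa MAD consistency constant (default 1.4826, consistent with the
#'   SD under normality).
#' @return z-score(s).
#' @examples
#' robust_z(1:5, 1)  # (3 - 1) / 1.4826 = 1.349
#' @export
robust_z <- function(sample, x, direction = c("reduction", "increase"),
                     kappa = 1.4826) {
  direction <- match.arg(direction)
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3L)
    stop_argument("robust_z needs >= 3 non-missing sample values (got %d)",
                  length(sample))
  med <- stats::median(sample)
  scale <- kappa * stats::mad(sample, center = med, constant = 1)
  if (scale == 0)
    stop_degenerate_dispersion("sample MAD is zero; robust z undefined")
  z <- (med - x) / scale
  if (direction == "increase") z <- -z
  z
}

# Internal scoring scale: kappa*MAD, falling back to the SD when the MAD
# degenerates to 0 while the values still vary (e.g. noise-free simulations
# where a majority of scores are exactly at the median). Errors only when all
# values are identical.
z_scale <- function(sample, kappa) {
  med <- stats::median(sample)
  scale <- kappa * stats::mad(sample, center = med, constant = 1)
  if (scale == 0) scale <- stats::sd(sample)
  if (is.na(scale) || scale == 0)
    stop_degenerate_dispersion(
      "all scores identical within a replicate; z-scores undefined")
  list(median = med, scale = scale)
}

#' Summarize per-replicate z-scores
#'
#' Arithmetic mean over non-missing replicate z-scores, with the count of
#' contributing replicates. All replicates missing yields `NA` with `n = 0`.
#'
#' @param z numeric vector of per-replicate z-scores (NA = missing).
#' @return List with `z` (mean) and `n` (number contributing).
#' @examples
#' summarize_replicates(c(1, NA, 3))  # z = 2, n = 2
#' @export
summarize_replicates <- function(z) {
  n <- sum(!is.na(z))
  list(z = if (n == 0L) NA_real_ else mean(z, na.rm = TRUE), n = n)
}

#' Pairwise replicate correlation
#'
#' Pearson correlation of per-siRNA scores between two replicates over
#' siRNAs measured in both ("pairwise complete"). A QC statistic: well-run
#' replicate experiments of this design correlate around 0.8.
#'
#' @param scored a `scored_screen` (from [score_screen()]), or a data.frame
#'   with columns `sirna_id`, `replicate`, `score`.
#' @param i,j replicate indices.
#' @return Pearson r.
#' @export
replicate_correlation <- function(scored, i, j) {
  df <- if (inherits(scored, "scored_screen")) scored$replicate_scores else scored
  xi <- df$score[df$replicate == i]
  names(xi) <- df$sirna_id[df$replicate == i]
  xj <- df$score[df$replicate == j]
  names(xj) <- df$sirna_id[df$replicate == j]
  common <- intersect(names(xi)[!is.na(xi)], names(xj)[!is.na(xj)])
  if (length(common) < 3L)
    stop_argument("need >= 3 siRNAs scored in both replicates (got %d)",
                  length(common))
  a <- xi[common]; b <- xj[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_degenerate_dispersion("zero variance in replicate %s",
                               if (stats::sd(a) == 0) i else j)
  stats::cor(a, b)
}

#' Quantile-quantile table of summarized z-scores
#'
#' Observed z-scores sorted ascending against standard-normal quantiles at
#' probability points (i - 0.5)/n; the data behind a QQ hit-distribution
#' plot.
#'
#' @param z numeric vector of summarized z-scores (NA dropped); needs >= 2.
#' @return data.frame with columns `theoretical` and `observed`, both
#'   non-decreasing.
#' @export
qq_table <- function(z) {
  z <- z[!is.na(z)]
  n <- length(z)
  if (n < 2L) stop_argument("qq_table needs >= 2 values (got %d)", n)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             observed = sort(z))
}

#' Per-plate matrices of summarized z-scores
#'
#' Lays summarized per-siRNA z-scores back onto the physical plates, one
#' `n_rows x n_cols` matrix per plate (the data behind a screen-wide image
#' plot). Sample wells carry their siRNA's z; control and empty wells are
#' `NA` in the z matrix and distinguished in the parallel `role` matrix
#' attached as attribute `"roles"` of each matrix.
#'
#' @param z named numeric vector of summarized z-scores (names are siRNA
#'   ids), as from `scored$sirnas`.
#' @param library an [sirna_library()].
#' @param layout a [plate_layout()].
#' @return Named list (one element per plate) of numeric matrices with
#'   dimnames rows `LETTERS`, columns `1..n_cols` and a `"roles"` character
#'   matrix attribute.
#' @export
plate_image_matrices <- function(z, library, layout) {
  ew <- effective_wells(layout, library)
  pw <- parse_well(ew$well, layout$n_rows, layout$n_cols)
  ew$row <- pw$row; ew$col <- pw$col
  lapply(split(ew, ew$plate), function(p) {
    m <- matrix(NA_real_, layout$n_rows, layout$n_cols,
                dimnames = list(LETTERS[seq_len(layout$n_rows)],
                                seq_len(layout$n_cols)))
    r <- matrix("empty", layout$n_rows, layout$n_cols,
                dimnames = dimnames(m))
    r[cbind(p$row, p$col)] <- p$role
    smp <- p[p$role == "sample", , drop = FALSE]
    m[cbind(smp$row, smp$col)] <- unname(z[smp$sirna_id])
    attr(m, "roles") <- r
    m
  })
}

#' Score a dual-channel screen
#'
#' The central preprocessing step: raw two-channel readouts become
#' per-siRNA summarized robust z-scores. Per replicate and plate, each
#' channel is normalized by the median of its sample wells; the per-well
#' activity/density ratio is formed and normalized by the plate's sample-well
#' ratio median (so that plate-wide and per-well multiplicative effects
#' cancel exactly); wells whose normalized density falls below
#' `config$mb_floor` are excluded (`"low_viability_signal"`); scores are
#' log2 ratios by default; per replicate, all sample-well scores (pooled
#' across the replicate's plates) are turned into robust z-scores
#' `(median - score) / (kappa * MAD)` — reduction-positive — and the
#' per-siRNA z is the mean over replicates. The density channel is scored
#' the same way on its own (log2 normalized density), yielding the `z_mb`
#' used by the viability filter and by the single-channel density analysis.
#'
#' @param screen a [screen_dataset()].
#' @param layout a [plate_layout()].
#' @param library an [sirna_library()].
#' @param config a [screen_config()].
#' @return An object of class `scored_screen`: list with `wells` (per-well
#'   table: normalized values, ratio, scores, z, exclusion reasons),
#'   `replicate_scores` (per-siRNA per-replicate scores and z),
#'   `sirnas` (per-siRNA summary: `z`, `n_replicates`, `z_mb`, placement),
#'   `correlations` (pairwise replicate correlation matrix on scores),
#'   `exclusions` (counts by reason), and the `config` echo.
#' @export
score_screen <- function(screen, layout, library, config = screen_config()) {
  stopifnot(inherits(screen, "screen_dataset"))
  ew <- effective_wells(layout, library)
  v <- screen$values
  key <- paste(v$plate, v$well)
  ewk <- paste(ew$plate, ew$well)
  idx <- match(key, ewk)
  if (anyNA(idx))
    stop_validation("readout at plate/well not covered by layout/library: %s",
                    paste(utils::head(unique(key[is.na(idx)]), 5),
                          collapse = "; "))
  v$role <- ew$role[idx]
  v$sirna_id <- ew$sirna_id[idx]
  v$gene <- ew$gene[idx]
  v <- v[v$role != "empty", , drop = FALSE]

  # wide per (replicate, plate, well)
  wk <- paste(v$replicate, v$plate, v$well)
  uk <- !duplicated(wk)
  w <- v[uk, c("replicate", "plate", "well", "role", "sirna_id", "gene")]
  rownames(w) <- wk[uk]
  w$erod <- NA_real_; w$mb <- NA_real_
  w[wk[v$channel == "EROD"], "erod"] <- v$value[v$channel == "EROD"]
  w[wk[v$channel == "MB"], "mb"] <- v$value[v$channel == "MB"]

  kappa <- config$mad_consistency_constant
  w$norm_erod <- NA_real_; w$norm_mb <- NA_real_
  w$ratio <- NA_real_; w$score <- NA_real_; w$mb_score <- NA_real_
  w$excluded <- NA_character_

  groups <- split(seq_len(nrow(w)), list(w$replicate, w$plate), drop = TRUE)
  for (g in groups) {
    role_vec <- stats::setNames(w$role[g], w$well[g])
    plate_id <- sprintf("%d (replicate %d)", w$plate[g][1L], w$replicate[g][1L])
    ne <- stats::setNames(w$erod[g], w$well[g])
    nm <- stats::setNames(w$mb[g], w$well[g])
    w$norm_erod[g] <- plate_median_normalize(ne, role_vec, plate_id)
    w$norm_mb[g] <- plate_median_normalize(nm, role_vec, plate_id)

    # raw per-well ratio (per-well effects cancel exactly), plate-normalized
    # by the sample-well ratio median; validity floor on normalized density
    raw_ratio <- w$erod[g] / ifelse(w$mb[g] == 0, NA, w$mb[g])
    low <- !is.na(w$norm_mb[g]) & w$norm_mb[g] < config$mb_floor
    raw_ratio[low] <- NA_real_
    w$excluded[g] <- ifelse(low, "low_viability_signal", NA_character_)
    smp <- w$role[g] == "sample" & !is.na(raw_ratio)
    if (sum(smp) < 3L)
      stop_normalize("plate %s: fewer than 3 valid sample-well ratios", plate_id)
    med_ratio <- stats::median(raw_ratio[smp])
    if (is.na(med_ratio) || med_ratio <= 0)
      stop_normalize("plate %s: sample ratio median is not positive", plate_id)
    w$ratio[g] <- raw_ratio / med_ratio
    if (config$score_on_log_ratio) {
      w$score[g] <- log2(w$ratio[g])
      w$mb_score[g] <- log2(w$norm_mb[g])
    } else {
      w$score[g] <- w$ratio[g]
      w$mb_score[g] <- w$norm_mb[g]
    }
  }

  # explicitly missing wells
  miss <- is.na(w$erod) | is.na(w$mb)
  w$excluded[miss & is.na(w$excluded)] <- "missing_value"
  w$score[miss] <- NA_real_
  w$mb_score[is.na(w$mb)] <- NA_real_

  # per-replicate pooled robust z over sample wells
  w$z <- NA_real_; w$z_mb <- NA_real_
  for (rep_i in sort(unique(w$replicate))) {
    in_rep <- w$replicate == rep_i
    smp <- in_rep & w$role == "sample" & !is.na(w$score)
    zs <- z_scale(w$score[smp], kappa)
    z <- (zs$median - w$score[in_rep]) / zs$scale
    if (config$direction == "increase") z <- -z
    w$z[in_rep] <- z
    smp_mb <- in_rep & w$role == "sample" & !is.na(w$mb_score)
    mb_scores <- w$mb_score[smp_mb]
    if (stats::sd(mb_scores) == 0) {
      # no density variation at all: nothing can be a density confound
      w$z_mb[in_rep] <- ifelse(is.na(w$mb_score[in_rep]), NA_real_, 0)
    } else {
      zm <- z_scale(mb_scores, kappa)
      w$z_mb[in_rep] <- (zm$median - w$mb_score[in_rep]) / zm$scale
    }
  }

  # per-siRNA per-replicate and summarized tables
  sw <- w[w$role == "sample", , drop = FALSE]
  rs <- data.frame(sirna_id = sw$sirna_id, gene = sw$gene,
                   replicate = sw$replicate, plate = sw$plate, well = sw$well,
                   score = sw$score, z = sw$z, z_mb = sw$z_mb,
                   stringsAsFactors = FALSE)
  rs <- rs[order(rs$sirna_id, rs$replicate, method = "radix"), ]
  rownames(rs) <- NULL

  ids <- sort(unique(rs$sirna_id), method = "radix")
  zmat <- matrix(NA_real_, length(ids),
                 length(unique(rs$replicate)),
                 dimnames = list(ids, NULL))
  zmat[cbind(match(rs$sirna_id, ids), match(rs$replicate,
                                            sort(unique(rs$replicate))))] <- rs$z
  zmbmat <- zmat
  zmbmat[] <- NA_real_
  zmbmat[cbind(match(rs$sirna_id, ids),
               match(rs$replicate, sort(unique(rs$replicate))))] <- rs$z_mb
  nrep <- rowSums(!is.na(zmat))
  sirnas <- data.frame(
    sirna_id = ids,
    gene = rs$gene[match(ids, rs$sirna_id)],
    plate = rs$plate[match(ids, rs$sirna_id)],
    well = rs$well[match(ids, rs$sirna_id)],
    z = ifelse(nrep == 0L, NA_real_, rowMeans(zmat, na.rm = TRUE)),
    n_replicates = as.integer(nrep),
    z_mb = ifelse(rowSums(!is.na(zmbmat)) == 0L, NA_real_,
                  rowMeans(zmbmat, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rownames(sirnas) <- NULL

  reps <- sort(unique(w$replicate))
  cm <- matrix(NA_real_, length(reps), length(reps),
               dimnames = list(reps, reps))
  diag(cm) <- 1
  rs_df <- rs
  if (length(reps) > 1L)
    for (a in seq_along(reps)) for (b in seq_along(reps)) if (a < b) {
      cm[a, b] <- cm[b, a] <- replicate_correlation(rs_df, reps[a], reps[b])
    }

  excl <- table(w$excluded[!is.na(w$excluded)])
  structure(list(wells = w, replicate_scores = rs, sirnas = sirnas,
                 correlations = cm,
                 exclusions = stats::setNames(as.integer(excl), names(excl)),
                 config = config),
            class = "scored_screen")
}

#' @export
print.scored_screen <- function(x, ...) {
  cat(sprintf("<scored_screen> %d siRNAs x %d replicates (%d wells)\n",
              nrow(x$sirnas), ncol(x$correlations), nrow(x$wells)))
  if (ncol(x$correlations) > 1L) {
    cc <- x$correlations[upper.tri(x$correlations)]
    cat(sprintf("  replicate correlations: %s\n",
                paste(sprintf("%.2f", cc), collapse = ", ")))
  }
  if (length(x$exclusions))
    cat(sprintf("  excluded wells: %s\n",
                paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.scored_screen <- function(object, ...) {
  z <- object$sirnas$z
  cat(sprintf("Summarized z over %d siRNAs: median %.3f, MAD %.3f, range [%.2f, %.2f]\n",
              sum(!is.na(z)), stats::median(z, na.rm = TRUE),
              stats::mad(z, na.rm = TRUE), min(z, na.rm = TRUE),
              max(z, na.rm = TRUE)))
  print(object)
  invisible(object)
}

#' @export
plot.scored_screen <- function(x, ...) {
  qq <- qq_table(x$sirnas$z)
  graphics::plot(qq$theoretical, qq$observed,
                 xlab = "standard normal quantile", ylab = "summarized z",
                 main = "hit distribution", pch = 20, cex = 0.4, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
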