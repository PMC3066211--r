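#' Simulation configuration for synthetic dual-channel screens
#'
#' Defines the generative model of a synthetic screen with known ground
#' truth, emulating the kinome screen design: 3 replicate experiments of 30
#' 96-well plates, 712 genes x 3 siRNAs, negative controls at A12, B12, G12,
#' H12 and positive (AhR-siRNA-like) controls at G1, H1. Per well,
#' `EROD = base_erod * plate_factor * edge * gene_effect_E * noise` and
#' `MB = base_mb * plate_factor * edge * gene_effect_M * noise'`, with
#' lognormal plate factors and measurement noise. Planted reporter-hit genes
#' multiply EROD only by `erod_effect` (when the siRNA is efficient);
#' viability genes multiply both channels by `viability_effect`; positive
#' controls multiply EROD only by `pos_control_effect`. Each siRNA draws its
#' efficacy once (probability `per_sirna_efficacy`): an inefficient siRNA
#' carries no effect, the screen's stated false-negative source.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical screens.
#' @param n_genes,sirnas_per_gene,n_replicates library and replicate design.
#' @param n_rows,n_cols plate geometry.
#' @param samples_per_plate occupied sample wells per plate (default 72,
#'   giving 30 plates for the default library).
#' @param neg_control_wells,pos_control_wells fixed control positions.
#' @param fraction_erod_hits,erod_effect fraction of genes planted as
#'   reporter hits and their multiplicative EROD reduction in (0, 1].
#' @param fraction_viability_genes,viability_effect fraction of genes whose
#'   knockdown reduces both channels, and the common multiplier.
#' @param per_sirna_efficacy probability q that a given siRNA achieves
#'   knockdown.
#' @param plate_effect_sd lognormal sigma of the per-plate factor.
#' @param edge_effect multiplier applied to border wells (default 1 = none).
#' @param noise_sd lognormal sigma of per-well measurement noise.
#' @param pos_control_effect EROD multiplier of the positive controls.
#' @param base_erod,base_mb baseline channel levels.
#' @param placement `"sequential"` (row-major fill, default) or `"shuffled"`.
#' @param kinetic emit 16-point kinetic fluorescence traces whose OLS slope
#'   is the EROD activity, instead of precomputed activities.
#' @param kinetic_points,kinetic_noise_sd trace length over 0-15 min and
#'   additive trace noise SD.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 712, sirnas_per_gene = 3,
                              n_replicates = 3, n_rows = 8, n_cols = 12,
                              samples_per_plate = 72,
                              neg_control_wells = c("A12", "B12", "G12", "H12"),
                              pos_control_wells = c("G1", "H1"),
                              fraction_erod_hits = 0.03, erod_effect = 0.4,
                              fraction_viability_genes = 0.10,
                              viability_effect = 0.4,
                              per_sirna_efficacy = 2 / 3,
                              plate_effect_sd = 0.15, edge_effect = 1,
                              noise_sd = 0.045, pos_control_effect = 0.05,
                              base_erod = 100, base_mb = 1,
                              placement = c("sequential", "shuffled"),
                              kinetic = FALSE, kinetic_points = 16,
                              kinetic_noise_sd = 0) {
  placement <- match.arg(placement)
  frac <- c(fraction_erod_hits, fraction_viability_genes, per_sirna_efficacy)
  if (any(frac < 0 | frac > 1))
    stop_argument("fractions and efficacy must lie in [0, 1]")
  if (fraction_erod_hits + fraction_viability_genes > 1)
    stop_argument("hit and viability fractions must not overlap the gene set")
  eff <- c(erod_effect, viability_effect, pos_control_effect)
  if (any(eff <= 0 | eff > 1))
    stop_argument("effects must lie in (0, 1]")
  if (any(c(plate_effect_sd, noise_sd, kinetic_noise_sd) < 0))
    stop_argument("noise SDs must be >= 0")
  n_sample_capacity <- n_rows * n_cols -
    length(neg_control_wells) - length(pos_control_wells)
  if (samples_per_plate > n_sample_capacity)
    stop_argument("samples_per_plate (%d) exceeds plate capacity (%d)",
                  samples_per_plate, n_sample_capacity)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 sirnas_per_gene = as.integer(sirnas_per_gene),
                 n_replicates = as.integer(n_replicates),
                 n_rows = n_rows, n_cols = n_cols,
                 samples_per_plate = as.integer(samples_per_plate),
                 neg_control_wells = neg_control_wells,
                 pos_control_wells = pos_control_wells,
                 fraction_erod_hits = fraction_erod_hits,
                 erod_effect = erod_effect,
                 fraction_viability_genes = fraction_viability_genes,
                 viability_effect = viability_effect,
                 per_sirna_efficacy = per_sirna_efficacy,
                 plate_effect_sd = plate_effect_sd, edge_effect = edge_effect,
                 noise_sd = noise_sd, pos_control_effect = pos_control_effect,
                 base_erod = base_erod, base_mb = base_mb,
                 placement = placement, kinetic = isTRUE(kinetic),
                 kinetic_points = as.integer(kinetic_points),
                 kinetic_noise_sd = kinetic_noise_sd),
            class = "simulation_config")
}

#' Simulate a complete dual-channel screen with known ground truth
#'
#' Draws a synthetic screen under the model of [simulation_config()].
#' Gene classes are assigned by exact counts (`round(fraction * n_genes)`
#' reporter hits and viability genes, disjoint, identities drawn from the
#' seeded generator); siRNA efficacies are drawn once per siRNA.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `screen` ([screen_dataset()]), `layout`
#'   ([plate_layout()]), `library` ([sirna_library()]) and `truth` (a
#'   data.frame of class `truth_table`: per gene `class` in
#'   `{erod_hit, viability, null}`; per-siRNA efficacy draws in attribute
#'   `"sirna_efficacy"`).
#' @export
simulate_screen <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- config$n_genes
  r <- config$sirnas_per_gene
  genes <- sprintf("KIN%04d", seq_len(g))

  n_hit <- round(config$fraction_erod_hits * g)
  n_via <- round(config$fraction_viability_genes * g)
  cls <- rep("null", g)
  pick <- sample.int(g, n_hit + n_via)
  cls[pick[seq_len(n_hit)]] <- "erod_hit"
  if (n_via > 0) cls[pick[n_hit + seq_len(n_via)]] <- "viability"

  sirna_id <- as.vector(t(outer(genes, seq_len(r),
                                function(a, b) sprintf("%s_s%d", a, b))))
  sirna_gene <- rep(genes, each = r)
  efficient <- stats::runif(length(sirna_id)) < config$per_sirna_efficacy

  layout <- plate_layout(config$n_rows, config$n_cols,
                         config$neg_control_wells, config$pos_control_wells)
  sample_wells <- names(roles(layout))[roles(layout) == "sample"]
  sample_wells <- sample_wells[seq_len(config$samples_per_plate)]
  n_sirna <- length(sirna_id)
  n_plates <- ceiling(n_sirna / config$samples_per_plate)
  slot <- seq_len(n_sirna)
  if (config$placement == "shuffled") slot <- sample(slot)
  plate_of <- (slot - 1L) %/% config$samples_per_plate + 1L
  well_of <- sample_wells[(slot - 1L) %% config$samples_per_plate + 1L]
  library <- sirna_library(data.frame(sirna_id = sirna_id, gene = sirna_gene,
                                      plate = plate_of, well = well_of,
                                      stringsAsFactors = FALSE),
                           sirnas_per_gene = r)

  ew <- effective_wells(layout, library)
  ew <- ew[ew$role != "empty", , drop = FALSE]
  pw <- parse_well(ew$well, config$n_rows, config$n_cols)
  on_edge <- pw$row == 1L | pw$row == config$n_rows |
    pw$col == 1L | pw$col == config$n_cols
  edge_mult <- ifelse(on_edge, config$edge_effect, 1)

  gene_cls <- cls[match(ew$gene, genes)]
  sirna_eff <- efficient[match(ew$sirna_id, sirna_id)]
  eff_e <- rep(1, nrow(ew))
  eff_m <- rep(1, nrow(ew))
  is_hit <- !is.na(gene_cls) & gene_cls == "erod_hit" & sirna_eff
  is_via <- !is.na(gene_cls) & gene_cls == "viability" & sirna_eff
  eff_e[is_hit] <- config$erod_effect
  eff_e[is_via] <- config$viability_effect
  eff_m[is_via] <- config$viability_effect
  eff_e[ew$role == "pos_control"] <- config$pos_control_effect

  nw <- nrow(ew)
  reps <- seq_len(config$n_replicates)
  vals <- vector("list", length(reps))
  traces <- if (config$kinetic) list() else NULL
  for (rep_i in reps) {
    pf <- exp(stats::rnorm(n_plates, 0, config$plate_effect_sd))
    noise_e <- exp(stats::rnorm(nw, 0, config$noise_sd))
    noise_m <- exp(stats::rnorm(nw, 0, config$noise_sd))
    erod <- config$base_erod * pf[ew$plate] * edge_mult * eff_e * noise_e
    mb <- config$base_mb * pf[ew$plate] * edge_mult * eff_m * noise_m
    vals[[rep_i]] <- data.frame(
      replicate = rep_i,
      plate = rep(ew$plate, 2L), well = rep(ew$well, 2L),
      channel = rep(c("EROD", "MB"), each = nw),
      value = c(erod, mb), stringsAsFactors = FALSE)
    if (config$kinetic) {
      tt <- seq(0, 15, length.out = config$kinetic_points)
      for (i in seq_len(nw)) {
        fl <- 10 + erod[i] * tt
        if (config$kinetic_noise_sd > 0)
          fl <- fl + stats::rnorm(length(tt), 0, config$kinetic_noise_sd)
        key <- sprintf("%d/%d/%s", rep_i, ew$plate[i], ew$well[i])
        traces[[key]] <- data.frame(time = tt, fluorescence = fl)
        # the dataset's EROD value is the slope the trace encodes
        vals[[rep_i]]$value[i] <- erod_slope(traces[[key]])
      }
    }
  }
  values <- do.call(rbind, vals)
  values$value <- pmax(values$value, 0)
  screen <- screen_dataset(values, traces = traces)

  truth <- structure(data.frame(gene = genes, class = cls,
                                stringsAsFactors = FALSE),
                     sirna_efficacy = data.frame(sirna_id = sirna_id,
                                                 gene = sirna_gene,
                                                 efficient = efficient,
                                                 stringsAsFactors = FALSE),
                     class = c("truth_table", "data.frame"))
  list(screen = screen, layout = layout, library = library, truth = truth)
}

#' Recovery metrics of a hit table against simulation ground truth
#'
#' @param hits a `hit_table` from [call_gene_hits()].
#' @param truth a `truth_table` from [simulate_screen()].
#' @param class_ planted class counted as positive (default `"erod_hit"`).
#' @return List with `sensitivity` (called planted / planted; `NA` when
#'   nothing was planted), `fdr` (non-planted calls / calls; 0 when no
#'   calls), `specificity`, `n_called`, `n_planted`.
#' @export
evaluate_recovery <- function(hits, truth, class_ = "erod_hit") {
  called <- hit_genes(hits)
  planted <- truth$gene[truth$class == class_]
  negatives <- truth$gene[truth$class != class_]
  tp <- length(intersect(called, planted))
  fp <- length(setdiff(called, planted))
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       fdr = if (length(called)) fp / length(called) else 0,
       specificity = if (length(negatives))
         1 - fp / length(negatives) else NA_real_,
       n_called = length(called), n_planted = length(planted))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> seed %d: %d genes x %d siRNA, %d replicates\n",
              x$seed, x$n_genes, x$sirnas_per_gene, x$n_replicates))
  cat(sprintf("  hits: %.1f%% (effect %.2f), viability: %.1f%% (effect %.2f), efficacy %.2f\n",
              100 * x$fraction_erod_hits, x$erod_effect,
              100 * x$fraction_viability_genes, x$viability_effect,
              x$per_sirna_efficacy))
  invisible(x)
}
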