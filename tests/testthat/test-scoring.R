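# Normalization, ratios, robust z-scores and QC statistics

test_that("erod_slope is the OLS slope of fluorescence against time", {
  expect_equal(erod_slope(data.frame(time = c(0, 5, 10, 15),
                                     fluorescence = c(100, 150, 200, 250))), 10)
  expect_equal(erod_slope(data.frame(time = c(0, 15),
                                     fluorescence = c(7, 7))), 0)
  # noisy 16-point trace against the closed-form least-squares slope
  set.seed(42)
  t <- seq(0, 15, length.out = 16)
  y <- 3 + 4 * t + rnorm(16)
  closed <- (sum(t * y) - length(t) * mean(t) * mean(y)) /
    (sum(t^2) - length(t) * mean(t)^2)
  expect_equal(erod_slope(cbind(t, y)), closed, tolerance = 1e-12)
  expect_error(erod_slope(data.frame(time = 1, fluorescence = 2)),
               class = "kinscreen_degenerate_trace_error")
  expect_error(erod_slope(data.frame(time = c(3, 3), fluorescence = c(1, 2))),
               class = "kinscreen_degenerate_trace_error")
})

test_that("control-percentage normalization sets the neg-control mean at 100%", {
  lay <- plate_layout()
  v <- setNames(rep(NA_real_, 96), all_wells(lay))
  v[c("A12", "B12", "G12", "H12")] <- c(80, 120, 100, 100)
  v["A1"] <- 55
  expect_equal(percent_of_neg_controls(v, lay)[["A1"]], 55)
  v[c("A12", "B12", "G12", "H12")] <- c(50, 50, 150, 150)
  v["A1"] <- 200
  expect_equal(percent_of_neg_controls(v, lay)[["A1"]], 200)
  v2 <- setNames(rep(7, 96), all_wells(lay))
  expect_true(all(percent_of_neg_controls(v2, lay) == 100))
  v[c("A12", "B12", "G12", "H12")] <- NA
  expect_error(percent_of_neg_controls(v, lay, plate = 9),
               class = "kinscreen_normalization_error")
})

test_that("plate-median normalization fixes the sample-well median at 1", {
  lay <- plate_layout()
  v <- setNames(rep(8, 96), all_wells(lay))
  expect_true(all(plate_median_normalize(v, lay) == 1))
  v3 <- setNames(rep(NA_real_, 96), all_wells(lay))
  v3[c("A1", "A2", "A3")] <- c(2, 4, 6)
  expect_equal(unname(plate_median_normalize(v3, lay)[c("A1", "A2", "A3")]),
               c(0.5, 1, 1.5))
  # property: output sample median is 1, against a direct median oracle
  for (seed in 1:5) {
    set.seed(seed)
    v4 <- setNames(rlnorm(96, 2, 0.5), all_wells(lay))
    out <- plate_median_normalize(v4, lay)
    smp <- out[names(out) %in% names(roles(lay))[roles(lay) == "sample"]]
    expect_equal(median(sort(smp)), 1, tolerance = 1e-12)
  }
  expect_error(plate_median_normalize(v3 * 0, lay),
               class = "kinscreen_normalization_error")
})

test_that("channel ratio cancels pure viability loss and floors low density", {
  expect_equal(channel_ratio(2, 1, 0.1)$ratio, 2)
  r <- channel_ratio(0.4, 0.4, 0.1)  # both channels reduced alike
  expect_equal(r$ratio, 1)
  expect_true(is.na(r$excluded))
  ex <- channel_ratio(0.5, 0.01, 0.1)
  expect_true(is.na(ex$ratio))
  expect_equal(ex$excluded, "low_viability_signal")
})

test_that("robust z matches the direct median/MAD computation", {
  expect_equal(robust_z(1:5, 1), 2 / 1.4826, tolerance = 1e-12)
  expect_equal(robust_z(1:5, 3), 0)
  expect_equal(robust_z(1:5, 1, direction = "increase"), -2 / 1.4826,
               tolerance = 1e-12)
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    v <- rnorm(n) * 10^sample(-2:2, 1)
    x <- rnorm(1)
    mad_ok <- mad(v) > 0
    if (mad_ok) {
      expect_equal(robust_z(v, x), oracle_robust_z(v, x), tolerance = 1e-9)
    }
  }
  expect_error(robust_z(rep(1, 5), 2),
               class = "kinscreen_degenerate_dispersion_error")
  expect_error(robust_z(c(1, 2), 1), class = "kinscreen_argument_error")
})

test_that("replicate summarization is a mean over non-missing replicates", {
  expect_equal(summarize_replicates(c(0.9, 1.0, 1.1)), list(z = 1, n = 3L))
  expect_equal(summarize_replicates(c(2.2, 2.2, 2.2))$z, 2.2)
  s <- summarize_replicates(c(1, NA, 3))
  expect_equal(s$z, 2); expect_equal(s$n, 2L)
  expect_true(is.na(summarize_replicates(c(NA_real_, NA))$z))
  # permutation invariance
  set.seed(1)
  v <- rnorm(5)
  expect_equal(summarize_replicates(v), summarize_replicates(rev(v)))
  expect_equal(summarize_replicates(v), summarize_replicates(sample(v)))
})

test_that("replicate correlation matches the closed-form Pearson formula", {
  df <- data.frame(sirna_id = rep(letters[1:4], 2),
                   replicate = rep(1:2, each = 4),
                   score = c(1, 2, 3, 4, 2, 4, 5, 4))
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(replicate_correlation(df, 1, 2), closed, tolerance = 1e-12)

  ident <- df; ident$score[5:8] <- ident$score[1:4]
  expect_equal(replicate_correlation(ident, 1, 2), 1)
  negd <- df; negd$score[5:8] <- -negd$score[1:4]
  expect_equal(replicate_correlation(negd, 1, 2), -1)
  flat <- df; flat$score[5:8] <- 1
  expect_error(replicate_correlation(flat, 1, 2),
               class = "kinscreen_degenerate_dispersion_error")
})

test_that("qq table pairs sorted z with standard-normal quantiles", {
  expect_error(qq_table(1), class = "kinscreen_argument_error")
  set.seed(7)
  z <- rnorm(1000)
  qq <- qq_table(z)
  expect_false(is.unsorted(qq$theoretical))
  expect_false(is.unsorted(qq$observed))
  expect_equal(qq$theoretical, qnorm((1:1000 - 0.5) / 1000))
  expect_lt(max(abs(qq$observed - qq$theoretical)), 0.5)
  expect_lt(mean(abs(qq$observed - qq$theoretical)), 0.05)
  # deviation shrinks with n (Monte-Carlo sanity)
  qq_small <- qq_table(rnorm(50))
  expect_lt(mean(abs(qq$observed - qq$theoretical)),
            max(abs(qq_small$observed - qq_small$theoretical)) + 0.2)
})

test_that("per-replicate z-scores have median 0 and scaled MAD 1", {
  sim <- small_screen(11)
  sc <- score_small(sim)
  w <- sc$wells
  for (r in 1:3) {
    z <- w$z[w$replicate == r & w$role == "sample" & !is.na(w$z)]
    expect_lt(abs(median(z)), 1e-9)
    expect_lt(abs(1.4826 * mad(z, constant = 1) - 1), 1e-9)
    zm <- w$z_mb[w$replicate == r & w$role == "sample" & !is.na(w$z_mb)]
    expect_lt(abs(median(zm)), 1e-9)
    expect_lt(abs(1.4826 * mad(zm, constant = 1) - 1), 1e-9)
  }
})

test_that("scoring is invariant to plate-wide and per-well rescaling", {
  sim <- small_screen(12)
  base <- score_small(sim)

  # whole plate (both channels, one replicate) times gamma
  scr <- sim$screen
  idx <- scr$values$replicate == 2 & scr$values$plate == 1
  scr$values$value[idx] <- scr$values$value[idx] * 3.7
  scaled <- score_screen(screen_dataset(scr$values), sim$layout, sim$library)
  expect_lt(max(abs(scaled$sirnas$z - base$sirnas$z), na.rm = TRUE), 1e-9)

  # single well, both channels, gamma in (0.2, 1]
  for (gamma in c(0.25, 0.5, 1)) {
    scr2 <- sim$screen
    idx2 <- scr2$values$replicate == 1 & scr2$values$plate == 2 &
      scr2$values$well == "C5"
    expect_equal(sum(idx2), 2)
    scr2$values$value[idx2] <- scr2$values$value[idx2] * gamma
    sc2 <- score_screen(screen_dataset(scr2$values), sim$layout, sim$library)
    expect_lt(max(abs(sc2$sirnas$z - base$sirnas$z), na.rm = TRUE), 1e-9)
  }
})

test_that("direction = increase flips the sign of every z-score", {
  sim <- small_screen(13)
  red <- score_small(sim, screen_config(direction = "reduction"))
  inc <- score_small(sim, screen_config(direction = "increase"))
  expect_equal(inc$sirnas$z, -red$sirnas$z, tolerance = 1e-12)
})

test_that("plate image matrices place z-scores at the library positions", {
  sim <- small_screen(14)
  sc <- score_small(sim)
  z <- setNames(sc$sirnas$z, sc$sirnas$sirna_id)
  mats <- plate_image_matrices(z, sim$library, sim$layout)
  expect_length(mats, 2)
  # round trip: cell (A,1) holds the z of the siRNA placed at A1 on plate 1
  s_a1 <- sim$library$sirna_id[sim$library$plate == 1 & sim$library$well == "A1"]
  expect_equal(mats[["1"]]["A", "1"], unname(z[s_a1]))
  # bookkeeping: finite cells == measured sample wells
  n_finite <- sum(vapply(mats, function(m) sum(is.finite(m)), 0L))
  expect_equal(n_finite, sum(!is.na(sc$sirnas$z)))
  # controls marked distinctly
  rl <- attr(mats[["1"]], "roles")
  expect_equal(rl["A", "12"], "neg_control")
  expect_equal(rl["G", "1"], "pos_control")
})

test_that("wells below the density floor are excluded, not scored", {
  sim <- small_screen(15)
  scr <- sim$screen
  idx <- scr$values$replicate == 1 & scr$values$plate == 1 &
    scr$values$well == "B2" & scr$values$channel == "MB"
  scr$values$value[idx] <- scr$values$value[idx] * 0.01
  sc <- score_screen(screen_dataset(scr$values), sim$layout, sim$library)
  w <- sc$wells
  row <- w[w$replicate == 1 & w$plate == 1 & w$well == "B2", ]
  expect_equal(row$excluded, "low_viability_signal")
  expect_true(is.na(row$score))
  expect_equal(unname(sc$exclusions["low_viability_signal"]), 1L)
  # the siRNA still gets a summarized z from the remaining replicates
  sid <- row$sirna_id
  expect_equal(sc$sirnas$n_replicates[sc$sirnas$sirna_id == sid], 2L)
})
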