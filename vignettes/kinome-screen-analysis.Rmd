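---
title: "Dual-channel RNAi screen analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-channel RNAi screen analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinscreen)
```

## The problem

Arrayed RNAi screens knock down one gene per well and read a phenotype per
well. In the design this package targets, MCF-7 cells in 96-well plates are
transfected with a kinome-wide siRNA library (712 genes, 3 independent
siRNAs per gene, one siRNA per well), induced with the AhR agonist TCDD, and
read on two channels: EROD activity (CYP1A1 reporter enzyme activity, the
slope of a kinetic resorufin fluorescence trace over 15 minutes) and
methylene blue absorbance (cell density). Each experiment spans 30 plates
and is repeated three times. Every plate carries four negative-control wells
(A12, B12, G12, H12: non-targeting siRNA or transfection reagent alone) and
two positive controls (G1, H1: siRNA against AhR, which abolishes EROD
without affecting density).

Two systematic problems dominate such data. First, plates differ from each
other by multiplicative factors (reagent batches, timing, reader drift).
Second, many knockdowns reduce cell number, which reduces EROD trivially;
without correction, every essential gene would look like a pathway hit. The
analysis below addresses the first by per-plate normalization and the second
by the activity/density ratio plus an explicit viability filter.

## The scoring model

Write $E_{pw}$ and $M_{pw}$ for the raw EROD and density readings of well
$w$ on plate $p$ within one replicate.

1. **Per-channel plate normalization.** Each channel is divided by the
   median over the plate's sample wells, giving $\tilde E_{pw}$ and
   $\tilde M_{pw}$ with sample-median 1. These normalized values feed the QC
   outputs and the density analysis.
2. **Validity floor.** A well with $\tilde M_{pw} < 0.1$ (under 10% of
   plate-typical density) has too few cells for its EROD reading to mean
   anything; it is excluded with reason `low_viability_signal` rather than
   allowed to produce an explosive ratio. Exclusion is a recorded value, not
   an error, and excluded wells are dropped from all downstream statistics
   with their counts reported.
3. **Ratio.** The per-well ratio is $R_{pw} = E_{pw} / M_{pw}$, normalized
   by the plate's sample-well ratio median. A knockdown that reduces both
   channels proportionally — a pure viability effect — cancels exactly in
   $R_{pw}$.
4. **Score.** $s_{pw} = \log_2$ of the normalized ratio (default), so
   reductions and increases are symmetric around 0.
5. **Robust z.** Per replicate, pooling all sample-well scores across that
   replicate's plates,
   $$z = \frac{\mathrm{median}(s) - s_{pw}}{1.4826\,\cdot\,\mathrm{MAD}(s)},$$
   reduction-positive: an siRNA that lowers reporter activity gets a
   positive z. By construction the per-replicate z distribution over sample
   wells has median 0 and scaled MAD 1.
6. **Summarization.** The per-siRNA z is the arithmetic mean over its
   non-missing replicates, with the count of contributing replicates kept.

The density channel is scored by the same machinery on
$\log_2 \tilde M_{pw}$ alone, yielding `z_mb`.

### Why the ratio is normalized as a ratio

The scoring step could equally have divided the two per-channel normalized
values ($\tilde E / \tilde M$); that differs from the normalized raw ratio
only by a per-plate constant. The raw-ratio form was chosen because it makes
two structural guarantees *exact* rather than approximate: multiplying every
well of a plate (both channels) by any $\gamma > 0$, or multiplying both
channels of a single well by $\gamma$, leaves every EROD z-score unchanged —
in the per-channel-first form a rescaled well can shift a channel's plate
median (an order statistic), perturbing every other well on the plate. The
test suite asserts both invariances at 1e-9. The per-channel normalized
values are still computed and reported; they back the QC exports, the
validity floor and the density z.

### Degenerate dispersion

`robust_z()` refuses a reference sample with MAD 0, since the score is then
undefined. Inside `score_screen()` a weaker fallback applies: when the
pooled scores have MAD 0 but still vary (more than half the scores exactly
equal — which happens in noise-free simulations where unperturbed wells all
score exactly 0), the scale falls back to the sample standard deviation, and
only a replicate whose scores are *all* identical is an error. A density
channel with no variation at all is treated as "nothing can be a density
confound": `z_mb` is 0 everywhere rather than an error, since a filter over
a constant channel has nothing to flag.

## Hit calling

With per-siRNA summarized z in hand:

1. siRNAs with $|z_{MB}| \ge c$ (default $c = 2$) are flagged as viability
   confounds and removed from candidacy. The published rule relied on the
   ratio plus visual exclusion; the explicit threshold makes the same intent
   reproducible, and $c = \infty$ recovers ratio-only behavior.
2. The remaining siRNAs are ranked by decreasing z, ties broken
   lexicographically by siRNA identifier (stable and reproducible, rather
   than inflating k), and the top $k = 150$ are selected.
3. A gene is a hit when at least $m = 2$ of its $r = 3$ siRNAs are selected
   — one concordant independent sequence is unlikely to be a shared
   off-target. The hit count can never exceed $\lfloor k/m \rfloor = 75$,
   and raising $m$ can only shrink the hit set.

Filtering *before* ranking follows the reading that density-affecting
siRNAs are excluded before the top scores are taken; the caller exposes the
filter so the other order (or none) can be run. Genes with a number of
scored siRNAs different from $r$ are kept with a completeness warning and
the rule applied to what is available. `density_hit_analysis()` applies the
identical machinery to `z_mb` (reduction of density scored positive, no
viability filter — density is the phenotype there).

One consequence worth stating plainly: under pure chance, with 2136 siRNAs
and $k = 150$, the number of a null gene's siRNAs in the top set is
hypergeometric, and the expected number of null genes with $\ge 2$ of 3
selected is $712 \cdot P(X \ge 2) \approx 10$. The concordance rule
suppresses single-siRNA artifacts; it does not make a ~7% selection window
false-positive-free. The simulation tests assert this closed-form chance
level rather than wishing it away.

## Enrichment

Hit lists are tested for term overrepresentation with the right-tailed
hypergeometric test (identical to a one-sided Fisher exact test on the 2×2
table), $P(X \ge k)$ for overlap $k$, term size $K$, hit-list size $n$ and
universe $N$. The universe defaults to the union of annotated genes, since
the original background is not recoverable; reported p-values therefore
depend on the supplied annotation, while the counts $k/K$ and the floored
coverage $\lfloor 100k/K \rfloor$ do not. Flooring (not rounding) matches
the published coverage cells (2/7 = 28%, 4/140 = 2%). Benjamini–Hochberg
adjustment runs over all terms passing the size filter, including terms
with zero overlap (their p = 1 still counts toward the number of tests);
only overlapping terms are displayed. The default minimum term size is 1,
as published coverage includes 1/1 terms.

## The synthetic-screen generator

`simulate_screen()` draws screens from a multiplicative signal model: per
well, channel value = baseline × plate factor × edge factor × gene effect ×
lognormal noise, with the plate factor shared by both channels of a plate
and the noise independent per channel. Planted reporter-hit genes multiply
EROD alone by `erod_effect` when the siRNA is efficient; viability genes
multiply both channels by `viability_effect`; positive controls multiply
EROD alone by `pos_control_effect` (0.05, an AhR-like knockdown); negative
controls carry no effect. Each siRNA draws efficacy once — not per
replicate — matching the screen's main false-negative mechanism of
inefficient duplexes that fail consistently.

Defaults encode the study's screen: 712 genes × 3 siRNAs, 3 replicates, 30
plates of 72 sample wells with the fixed control wells, 3% planted hit
genes (the published hit rate), 10% viability genes, effect multipliers of
0.4, efficacy $q = 2/3$, `plate_effect_sd` 0.15, `noise_sd` 0.045. The
noise level was set analytically: the replicate correlation of log-ratio
scores is approximately
$\mathrm{Var}(signal) / (\mathrm{Var}(signal) + 2\sigma^2_{\log_2})$, and
with 2% of siRNAs carrying a $\log_2(0.4) \approx -1.32$ effect, $\sigma =
0.045$ puts the correlation near 0.80 — the published QC range (0.78–0.81).
Realized correlations on default screens land at 0.79–0.82.

What the generator does *not* model: siRNA off-target seed effects,
transfection-efficiency gradients, dose–response pharmacology, or spatial
structure beyond an optional uniform edge multiplier. Tests passing on
simulated screens therefore demonstrate the pipeline's statistical
machinery — normalization algebra, rule combinatorics, recovery under the
declared noise model — not robustness to every artifact of real plates.

Recovery under the defaults has a closed-form ceiling: a planted gene is
callable only if at least 2 of its 3 siRNAs are efficient, probability
$3q^2(1-q) + q^3 = 20/27 \approx 0.741$ at $q = 2/3$. Measured sensitivity
over 50 seeds is slightly above (chance promotion of inefficient siRNAs
into the top 150 roughly offsets viability-filter false flags); at $q = 1$
with zero noise, recovery is exact and no pure-viability gene is ever a
reporter hit, because the ratio cancels the effect identically.

## Numerical and I/O choices

- Kinetic traces are reduced by unweighted OLS over all points in the 0–15
  minute window; no lag-phase trimming. A trace with fewer than two
  distinct time points is a degenerate-trace error.
- Well addresses are row letter + 1-based column, no leading zeros ("A1").
- Missing wells are carried as explicit `NA` and never imputed; every
  statistic excludes them and reports exclusion counts.
- Readout tables round-trip at 17 significant digits (bit-exact); derived
  result tables are written at 6 significant digits.
- All tie-breaks (ranking, hit-table order, enrichment order) are
  deterministic via radix sort on identifiers, so identical inputs give
  byte-identical outputs.
- `hit_rate_percent()` rounds half up, so a tie like 12.5% reports as 13.

## Problem sizes in the test suite

Unit tests run on 40-gene, 2-plate screens; the structural, invariance and
recovery suites run full-geometry screens (2136 siRNAs, 30 plates, 3
replicates) over 20–50 seeds, which completes in well under a minute of
simulation time because the generator and scorer are vectorized. The
hypergeometric oracle is checked exhaustively against enumeration of all
draw outcomes for every universe size up to 12.

## Known limitations

- The published per-siRNA EROD z-scores were never deposited, so the real
  screen's hit table cannot be recomputed; the packaged 22-gene hit list is
  used as published input where the downstream arithmetic (hit rate,
  coverage) is exercised.
- The published enrichment p-values depend on an unknown background
  universe and term catalog and are deliberately not reproduced; the
  packaged annotation is synthetic except for term names, sizes and hit
  memberships.
- No B-score/median-polish or spatial correction is applied; the simulator
  can generate edge effects to study their consequence, but correcting them
  is out of scope.
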