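---
title: "Cell-cycle profiling of compound screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle profiling of compound screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleprof)
library(dplyr)
```

# The method

cycleprof implements a cell-cycle-based phenotypic screening cascade. A
DNA-selective stain gives each cell a fluorescence signal proportional to its
DNA mass, so a well's intensity distribution is a mixture of a 2N (G1) peak,
a 4N (G2/M) peak, an S-phase plateau between them, and a sub-G1 debris band
from apoptotic fragmentation. The pipeline:

1. **Gating** converts each well's per-cell intensities into the four phase
   percentages `<G1, S, G2/M, subG1>` — the well's *cell-cycle fingerprint*.
2. **CCI scoring** subtracts the plate's DMSO (vehicle) reference fingerprint
   and takes the Euclidean norm,
   `CCI = sqrt(RG1^2 + RS^2 + RG2M^2 + RsG1^2)`,
   a single number measuring how strongly a compound perturbs the cell cycle.
   Compounds with `CCI > 10` (percent-point scale) are profile hits.
3. **Viability** normalises end-point luminescence to the DMSO mean
   (`100 * raw / dmso_mean`) and calls a compound cytotoxic when its percent
   viability falls more than 3 sample standard deviations below the DMSO
   controls.
4. **Potency** fits a four-parameter logistic (4PL) curve
   `response = bottom + (top - bottom) / (1 + (dose/EC50)^hill)`
   to 8-point dilution series and keeps compounds with `EC50 < 20` uM.
   `ECf = EC50 * (f/(100-f))^(1/hill)` derives e.g. the EC90 for
   short-exposure follow-up.
5. **Clustering** groups the final hits by complete-linkage agglomerative
   clustering on the *raw* fingerprint percentages (Euclidean distance); a
   per-fingerprint Z-score transform is applied afterwards purely for heatmap
   display.
6. **Plate QC** uses the Z' factor,
   `Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`,
   on positive- vs negative-control readouts; values above 0.5 indicate a
   robust assay.

The hit sets are nested by construction — potency hits ⊆ viability hits ⊆
CCI hits — mirroring the funnel a screening campaign walks down.

# The synthetic-data generator

`simulate_well()` draws phase labels from a multinomial in the true
fractions, then intensities per phase:

* G1: Normal(`g1_mean`, `cv * g1_mean`), truncated positive;
* G2/M: Normal(`2 g1_mean`, `2 cv g1_mean`) — DNA mass doubles;
* S: Uniform between the two peak means, with multiplicative Normal(0, `cv`)
  noise — the standard idealisation of a DNA-content histogram's inter-peak
  plateau;
* sub-G1: Uniform on `(0.25 g1_mean, g1_mean (1 - 2 cv))` — a debris band
  kept clear of the G1 peak so the ground truth itself is unambiguous.

Defaults are chosen to be realistic for a 384-well imaging-cytometry screen:
`g1_mean = 100` arbitrary units, `cv = 0.05` (peak CVs of 3–8% are typical
for DNA stains), `n_events = 5000` cells per well (instrument capture counts
are rarely published; 5000 is a free parameter on the order of a confluent
384-well field), 16 DMSO wells per plate, and a DMSO composition of
(54% G1, 10% S, 31% G2/M, 5% sub-G1) — inside the ranges expected for
unperturbed cycling cancer cells (just over half in G1, ~10% S, ~30% G2/M,
<5% sub-G1). Positive-control wells default to a strong G2/M arrest
(82% G2/M), the phenotype of an antimitotic control.

Per-well seeds are a deterministic 32-bit hash of `(plate_seed, well_id)`,
so any well can be regenerated independently of simulation order and results
are identical across platforms.

What the generator does **not** emulate: doublets and clumps, optical
vignetting and focus artifacts, >4N aneuploid or endoreduplicating
populations, staining batch effects, and edge effects across the plate.
Passing recovery tests on this generator therefore demonstrates the
correctness of the gating and scoring machinery under the stated mixture
model — not robustness to every artifact of real cytometry data. Mixture
deconvolution (Watson / Dean–Jett–Fox) of overlapping S-phase is likewise
out of scope; gates are hard boundaries.

The dose-response generator uses the 8-point final-concentration grid
50, 12.5, 3.125, 0.781, 0.26, 0.065, 0.016, 0.004 uM — the screen's printed
stock dilution series scaled to a 50 uM top concentration. (The series
contains one 3-fold step; it is reproduced as printed rather than idealised
to exact 4-fold steps.)

# Gating: numerical choices

* **Histogram**: 128 half-open bins `[lo, hi)` (last bin closed) over
  `[0, 1.05 * q99.5]` of the intensities — explicit conventions so counts
  are bit-reproducible.
* **Peak detection**: counts are smoothed with a 3-bin moving average;
  local maxima are found on the smoothed profile and each peak is then
  snapped to the raw-count argmax within one bin (smoothing can drag a
  sparse peak's apex onto a neighbour). The tallest peak anchors the search:
  a companion in the DNA-mass window `[1.8, 2.2] x` its position makes it
  G1; a companion at `~0.5 x` (a G2/M-arrested well, where the 4N peak
  dominates) makes the *lower* peak G1. With no companion, G2 is synthesised
  at exactly `2 x g1_peak`. Equal-height ties resolve to the leftmost peak.
* **Peak width**: `sigma = FWHM / 2.355`, with the boxcar-smoothing
  (`(2/3) bw^2`) and binning (`bw^2/12`) variance inflation subtracted, so
  the estimate is unbiased for a Gaussian peak; fallback
  `sigma = cv_assumed * peak` when no half-max crossing resolves.
* **Gates**: `b0 = g1_peak - k sigma1`, `b1 = g1_peak + k sigma1`,
  `b2 = g2_peak - k sigma2`; sub-G1 `< b0`, G1 `[b0, b1)`, S `[b1, b2)`,
  G2/M `>= b2` (events above 4N count as G2/M). Every event is assigned, so
  fractions sum to exactly 1. Empty wells and flat histograms raise explicit
  gating errors carrying the well id; overlapping gates (`b1 >= b2`) are
  rejected rather than silently clipped.

**Why `k = 2` and not a wider gate.** The S-phase plateau abuts both peaks,
so everything within `k sigma` of a peak is claimed by that peak. Widening
the gate trades S-phase mass for G1/G2M tail capture: at `cv = 0.05`, a
2.5-sigma gate swallows ~37% of the S band and biases S by about -3.3
percent points — structurally, independent of how many cells are measured —
while `k = 2` balances the leakage terms and keeps the mean per-phase
recovery error within 1.5 points (and the per-phase bias bound of 2 points
that the test suite asserts). For the same reason per-event label agreement
with the generator has a ceiling: even at `cv = 0.01` boundary-adjacent
events are inherently ambiguous (~1%), so the suite asserts 98% agreement,
not an arbitrarily high figure.

# CCI and hit selection

The DMSO reference is the component-wise **mean** of a plate's DMSO-well
fingerprints, computed **per plate** so plate-level shifts cancel; the
aggregation rule is a design choice (median would also be defensible; the
mean matches how screening QC statistics are usually pooled). All CCI
arithmetic is on the percent (0–100) scale so reported magnitudes are
native to published phase tables. Hit selection uses strict `CCI > cutoff`
with deterministic ordering (CCI descending, alphabetical ties).

An unperturbed compound's CCI is not zero — gating noise and the finite
DMSO reference put the noise floor at a few points with 5000 events/well —
which is why the conventional cutoff of 10 points comfortably separates
genuine 15–20-point profile shifts from noise.

# Dose-response fitting

The 4PL is fit by bounded Levenberg–Marquardt least squares on the log10
dose scale, multi-started over EC50 initialisations at the geometric mean of
the doses and every interior dose; the best-RSS converged start wins. Eight-
point grids make multi-start both sufficient and deterministic — no global
optimiser, no randomness. A fit is flagged non-converged (no EC50 claimed)
when the fitted curve moves less than 5% of the observed response span
across the dose grid, when the Hill slope collapses to zero, or when the
asymptotes come out in the rising orientation (`top <= bottom`) — the
fitter targets inhibitory viability curves. Fewer than 4 distinct doses and
all-equal responses are rejected outright. RSS is reported; confidence
intervals are out of scope.

# Clustering and display

Distances are Euclidean on raw percentages; linkage is complete
(inter-cluster distance = maximum pairwise member distance), computed via
`stats::hclust`, with merge heights exposed as a tidy table and the
dendrogram exportable as Newick. An exhaustive brute-force agglomerator in
the test suite verifies merge heights on all instances with n ≤ 8.

The Z-score transform is **row-wise** by default: each drug's four phase
values are centred and scaled by their own mean and sample SD (n − 1,
consistent with the QC module). "Across the four phases" is genuinely
ambiguous between row-wise and column-wise scaling; only the display is
affected — clustering always uses raw fingerprints — so both are offered
(`margin = "column"`), with row-wise the default. Zero-variance rows map to
all-zero Z-scores with a warning rather than NaN.

# Chemical similarity networks

Bit fingerprints (e.g. FP2) are **inputs**, not computed here: similarity
values depend on the fingerprinting implementation and the structure
source, so decoupling keeps the module testable offline. Tanimoto
similarity `|A ∩ B| / |A ∪ B|` is defined as 0 for two empty sets. The
network keeps isolated nodes and weights edges by similarity; the default
threshold of 0.5 is a conventional mid-scale choice, not a published value.
Exports: GraphML and Cytoscape SIF.

# Problem sizes in the test and acceptance runs

The packaged checks simulate at desk scale: 50 seeded wells of 5000 events
for gating recovery; 50 noisy dilution series (5% CV, 3 replicates) for EC50
recovery; and 96-compound plates (20 truly shifted by 20 points, 16 DMSO
wells, 8 positive controls) for end-to-end hit recovery — sizes chosen so
the full suite runs in minutes on one CPU while keeping every estimate's
Monte-Carlo error well inside the asserted bounds.

# Known limitations

* Hard gates cannot split the S-phase mass that overlaps the peaks; phase
  fractions carry a small model bias (documented above) that mixture
  modelling would remove at the cost of distributional assumptions.
* The Z' QC in `run_screen()` uses the positive-control G2/M percentage as
  its readout; with no positive controls on a plate, QC is skipped.
* The CCI is a pure Euclidean distance: it weighs all four phases equally
  and ignores correlations between them (no Mahalanobis variant), and hit
  calling is a fixed cutoff, not a null-distribution test.
* Published screen-level figures that depend on unpublished raw data (the
  original plate readings, compound structures) cannot be recomputed; the
  formulas involved are unit-tested instead.

```{r example, eval = FALSE}
# a complete synthetic screen, end to end
sim <- simulate_screen(n_compounds = 96, n_shifted = 20, seed = 11)
scr <- run_screen(screen_config(seed = 11), sim$cytometry,
                  sim$viability_plate, sim$potency)
scr
plot_cci(scr$cci)
plot_fingerprint_heatmap(scr$tree, scr$zmatrix)
```
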