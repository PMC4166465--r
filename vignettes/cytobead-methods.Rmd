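---
title: "Models and methods behind cytobead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytobead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobead)
```

# The assay being modelled

Anti-neutrophil cytoplasmic antibodies (ANCA) are screened by indirect
immunofluorescence (IIF) on ethanol-fixed neutrophils and confirmed by
antigen-specific immunoassays against proteinase 3 (PR3) and myeloperoxidase
(MPO). The multiplexed format this package models combines both steps in one
well: neutrophil substrate for pattern reading, plus three microbead
populations read in the same image — 9 µm PR3-coated and 15 µm MPO-coated
beads identified in a red channel, and 12 µm solid-green reference beads
that anchor the size scale. Bound antibody shows as a green *halo* on the
analyte bead surface; halo mean fluorescence intensity (MFI) is the
quantitative readout, converted to IU/mL through a lot-specific
five-parameter logistic (5PL) master curve. The cell compartment yields the
IIF call — cytoplasmic (C), perinuclear (P) or negative — and, through a
pattern-dependent calibration, an estimate of the classical endpoint titer
from the single screening dilution (1/20 by default).

Because the physical assay needs sera, slides and a microscope, the package
ships a synthetic-well generator with exact ground truth. Everything
downstream — detection, quantification, titer estimation, agreement
statistics — treats a rendered well exactly as it would treat a real one.

# The synthetic generator

`render_sample()` draws a three-plane field (DAPI, GREEN, RED) for one
serum. The defaults emulate a 40x objective: 0.25 µm/pixel on a
1024 × 1024 sensor, so a 9 µm bead spans 36 pixels. Objects are placed by
rejection sampling with per-object exclusion radii so that no measurement
annulus or cytoplasmic band overlaps a neighbour; an overfull field raises
an explicit placement error rather than silently overlapping objects.

Two fixed monotone 5PL curves drive all signal amplitudes, so every
simulated quantity has a known truth:

* **Bead curve** (`true_bead_curve()`): halo amplitude vs analyte
  concentration; floor 100 a.u. at zero dose, saturation 5000 a.u.,
  C = 10 IU/mL, B = 1.2, G = 1. The floor is the assay blank: even a
  negative serum leaves a faint rim.
* **Cell curve** (`true_cell_curve()`): staining amplitude vs the
  dimensionless strength `titer / dilution`; floor 0, saturation
  4000 a.u., C = 250, B = 1, G = 1. The scale is chosen so that the
  amplitude at a serum's endpoint dilution (strength 1) is ~16 a.u.,
  of the order of the detection threshold — a serum titrates out where
  its titer says it should, which is what makes single-dilution titer
  estimation and classical serial-dilution reading mutually consistent in
  the simulation.

Cells are lobulated nuclei (2–4 overlapping ellipses, a deliberate
caricature of neutrophil morphology) with pattern-specific green staining:
P-pattern sera light up a 1 µm perinuclear band with a dim (15%) diffuse
cytoplasm; C-pattern sera light up the cytoplasmic shell (1–4 µm from the
nucleus) with discrete bright granules over a dim base, sparing the
immediate perinuclear band — a stylized but workable rendering of
"granular cytoplasmic" staining. Per-cell brightness jitters by a 10%
log-normal factor.

The camera model applies, in order, a constant background (20 a.u.),
Poisson shot noise (gain 1 a.u./photo-electron), Gaussian read noise
(SD 2 a.u.) and Gaussian PSF blur (sigma 0.3 µm). All four are
configurable and can be zeroed, which yields pixel-exact geometry used by
the oracle tests. Rendering is bit-deterministic given
(`sample_spec`, `simulation_config`): the RNG state is seeded from
`rng_seed` and restored afterwards.

One rendering choice deserves a note. The halo is drawn as an annulus
spanning `(r − 0.5, r + 2.5]` pixels rather than exactly `[r, r + 2]`:
the measurement annulus is anchored on an area-equivalent radius estimate
with sub-pixel jitter, and against a hard-edged 2-pixel ring every 0.1 px
of radius error swaps bright ring pixels for dark ones (several percent of
signal). Letting the rendered halo bleed half a pixel past the nominal rim
band makes the stated measurement well-posed; physically, surface staining
has no sub-pixel edge either.

What the generator does **not** emulate: focus drift, illumination
gradients, bead clumping and doublets, autofluorescent debris,
lot-to-lot antigen variation, or interfering antibody mixtures. Passing
the recovery tests therefore demonstrates that the algorithms are correct
and well-calibrated under an idealized but noisy imaging model — not that
they would survive every artifact of a physical slide.

# Measurement

**Beads.** Analyte candidates are segmented from the RED plane, reference
candidates from solid GREEN objects. Segmentation is a global
median + 5·MAD threshold followed by a per-object re-threshold at half the
object's peak amplitude, which puts the measured edge of a blurred disk at
its true radius; diameters are area-equivalent. Candidates must be round
(circularity ≥ 0.8) and 6–18 µm; green candidates must additionally be
filled (halo rings and cell staining are annular) and carry no red or DAPI
signal. Size demultiplexing first rescales all diameters by
`median(reference diameter) / 12 µm`, then calls PR3 below 10.5 µm and MPO
above 13.5 µm — the midpoints of the nominal 9/12/15 µm ladder — with a
dead zone in between whose candidates are excluded rather than guessed.

**Halos.** `measure_halo()` is the mean GREEN intensity in the annulus
`[r, r + 2 px]` minus the mean in a local background annulus
`[r + 4, r + 6 px]`, floored at zero. Beads whose background annulus
leaves the image are skipped with a warning. Under the default PSF the
measured MFI is a fixed fraction (~0.54) of the rendered amplitude; this
attenuation cancels in quantification because master curves are fitted to
*measured* standards.

**Cells.** Nuclei are segmented from DAPI (global threshold, watershed on
the distance map with a 1.5 µm merge tolerance so nuclear lobes stay
whole, then a per-nucleus half-max edge refinement). Each nucleus defines
a 1 µm rim band and a 1–4 µm cytoplasmic band; both are summarized on
GREEN after subtracting the image background median. Granularity is the
coefficient of variation of the cytoplasmic band.

**Pattern rule.** A cell is positive when either band reaches the
positivity threshold (3 × MAD of the GREEN background — scaling the image
rescales the threshold, so calls are gain-invariant). Positive cells are
called P when rim/cytoplasm ≥ 1.5, C when cytoplasm/rim ≥ 1.5 *and*
granularity > 0.3; cells in between do not vote. The sample call is the
majority vote, or negative when fewer than 20 cells are positive. The
ratio, granularity threshold and vote minimum are arguments, not
constants: the production descriptor set of the commercial interpretation
systems is proprietary, so this rule is a documented, configurable
stand-in.

**Validity.** A readout requires ≥ 50 analyte beads and ≥ 20 cells;
short wells raise a typed error carrying the observed counts instead of
returning a silently degraded measurement.

# Quantification

The 5PL response is `y = D + (A − D) / (1 + (x/C)^B)^G` with A the
zero-dose asymptote. `fit_5pl()` weights residuals by `1/y²` (fluorescence
error is roughly multiplicative), seeds from the data and from a 4PL fit,
starts from several asymmetry values and keeps the lowest weighted RSS,
with shape parameters confined to a broad admissible box (B, G in
[0.2, 5], C within a factor 8 of the standard range). Two facts about the
5PL shaped these choices. First, the model is monotone for every
admissible parameter set, so the post-fit monotonicity check can only
reject numerically pathological fits. Second, its likelihood has a ridge:
C and G trade off almost freely when the curve is shallow. With the
built-in bead curve (B = 1.2) and 2% measurement noise the *raw* C
parameter is unrecoverable (median error ≈ 40% for the exact weighted
MLE), even though the fitted *curve* — and hence every back-calculated
concentration — is excellent. The parameter-recovery study in the
acceptance suite therefore uses a steep calibrator (B = 3) whose eight
standards bracket both asymptotes (C/8 to 16 C), conditions under which C
is identifiable to a few percent; concentration round-trips are tested on
the shallow curve regardless, because they are ridge-invariant.

Run-to-run drift is corrected by `recalibrate_two_point()`: an affine
response transform `y' = s·y + t` solved from two adjusters of known
concentration, applied to the asymptotes only (shape is lot property).
`s ≤ 0` — a response inversion — is refused. Concentrations standardize to
percent of the top standard (`standardize_percent()`), and decisions use
inclusive cut-offs of 0.9 IU/mL (8.4%) for PR3 and 3.0 IU/mL (19.3%) for
MPO; the per-analyte top standards are derived from those printed pairs,
which keeps IU and percent decisions identical by construction. Precision
is summarized by `assay_cv()` (sample SD over mean; inter-assay pools
per-day means first) and `functional_sensitivity()` interpolates the
20%-CV crossing of a precision profile linearly in log concentration.

# Single-dilution titers

Sera with the same endpoint titer but different patterns give different
MFIs at 1/20, so `fit_titer_model()` learns a separate monotone map per
pattern: isotonic regression of log2 titer on log(MFI + 1), evaluated by
linear interpolation between the fitted knots with flat extrapolation.
Isotonic regression was chosen precisely because monotonicity is then true
by construction, not an assumption to verify. Predictions snap to the
nearest rung of the doubling ladder {10, 20, …, 5120}; exact log2
midpoints snap *down* (the conservative titer), an MFI below the training
range or a negative pattern returns the "≤10" bin, which is treated as a
real rung one step below 20 — consistent with its inclusion in the
collapsed 6 × 6 agreement table. `classical_endpoint_titer()` implements
the reference reading (highest positive dilution) so simulated serial
dilutions can be scored both ways.

# Agreement statistics

`cohens_kappa()` and `weighted_kappa()` share one engine (agreement
weights; identity weights recover Cohen's kappa) with the asymptotic
Fleiss–Cohen–Everitt standard error; on the packaged validation tables the
resulting intervals reproduce the published ones to three decimals, which
is why no bootstrap was added. Weighted kappa defaults to quadratic
disagreement weights `((i−j)/(k−1))²`: on the collapsed titer table the
quadratic statistic reproduces the published value (0.985) and linear
weighting (0.948) does not, settling which convention the original
analysis used. Note that weighted kappa is order-sensitive: it is
invariant to reversing the category order but not to arbitrary relabeling,
unlike the unweighted statistic.

`mcnemar_paired()` reports the paired difference `100(b − c)/N` with a
continuity-corrected Wald interval and an exact two-sided binomial p-value
(discordant counts in these comparisons are small; the chi-square version
is available behind `exact = FALSE`). `roc_analysis()` computes the rank
(Mann–Whitney) AUC, a DeLong variance interval, and the Youden-optimal
cut-off with ties broken toward higher specificity. The printed assay
cut-offs are shipped as constants rather than recomputed claims, since the
criterion that produced them is not stated with the data needed to
reproduce it.

# Problem sizes and numerical choices

The test and acceptance suites size their simulations as follows: bead
recovery on seven full default wells (525 beads); pattern recovery on 200
cell-compartment wells (704², 24 cells each) at saturating titer; titer
recovery on 36 training plus 200 test wells spanning the full ladder;
5PL Monte-Carlo on 50 replicate fits. These sizes give binomial/Monte-Carlo
resolution comfortably finer than the thresholds being tested (e.g. a
95% pattern criterion is estimated to ±1.5% SE at n = 200).

Degenerate inputs are handled explicitly rather than coerced: empty
images yield empty detections; blank planes are "no objects", not errors;
missing reference beads, insufficient object counts, out-of-range
inversions, inverted recalibrations and off-ladder titers each raise a
distinct condition class. Ties: majority-vote ties go to C; Youden ties
go to the higher-specificity threshold; titer midpoints snap down.

# Limitations

The pattern rule and titer algorithm are documented stand-ins for
proprietary production algorithms; their parameters are exposed so users
can re-tune them against real images. The generator's realism limits are
listed above — in particular, simulated accuracy figures (98% bead
classification, 95% pattern and titer concordance) characterize the
algorithms under the stated noise model, not clinical performance.
Real-sera quantities from the validation study (ROC AUCs, assay CVs,
cohort prevalences) require physical samples and are deliberately out of
scope; the packaged validation tables exist so the *statistics* layer can
be verified against published numbers.
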