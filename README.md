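# cytobead

Automated interpretation of multiplexed ANCA assays that combine
indirect immunofluorescence (IIF) on ethanol-fixed neutrophils with
antigen-coated microbead immunoassays in a single well — plus a
synthetic-well generator so the whole pipeline runs and validates without
a microscope.

Anti-neutrophil cytoplasmic antibodies (ANCA) against proteinase 3 (PR3)
and myeloperoxidase (MPO) are the serological hallmark of ANCA-associated
vasculitis. Conventional work-up needs two assays: IIF screening (the
C-ANCA / P-ANCA pattern) and antigen-specific confirmation. In the
multiplexed format modelled here, one fluorescence image contains both:
neutrophils for the pattern call, and three size-demultiplexed bead
populations (9 µm PR3, 15 µm MPO, 12 µm reference) whose green surface
*halo* intensity quantifies the bound antibody.

The package is aimed at assay developers and image-analysis people who
need a testable, fully ground-truthed model of this readout chain.

## What it implements

* **`synth_*` / `render_sample()`** — synthetic wells (DAPI/GREEN/RED
  planes + JSON ground truth): lobulated nuclei with cytoplasmic-granular
  or perinuclear-rim staining, bead populations with halos following a
  built-in true 5PL dose response, Poisson + Gaussian + PSF camera model;
  dilution series and cohort generators; multi-page TIFF I/O.
* **`detect_beads()` / `detect_cells()` / `analyze_well()`** — bead
  detection and size demultiplexing against the reference population,
  annulus-based halo MFI, nucleus segmentation, rim/cytoplasm
  measurement, pattern call by a configurable ratio-and-granularity rule,
  with explicit minimum object counts (50 beads, 20 cells).
* **Quantification** — 5PL master curves
  `y = D + (A − D)/(1 + (x/C)^B)^G` fitted by weighted
  Levenberg–Marquardt (`fit_5pl()`), exact inversion, two-point run
  recalibration, percent-of-top-standard scaling, inclusive cut-offs
  (PR3 0.9 IU/mL = 8.4%, MPO 3.0 IU/mL = 19.3%), assay CVs and
  functional sensitivity.
* **Endpoint titers from one dilution** — per-pattern isotonic maps from
  log MFI at 1/20 to the log2 titer ladder {≤10, 20, …, 5120}
  (`fit_titer_model()`, `predict_titer()`), classical serial-dilution
  reading, and 10×10 / collapsed 6×6 agreement tables.
* **Agreement statistics** — Cohen's kappa and quadratic/linear weighted
  kappa with asymptotic CIs, exact McNemar test with paired-difference
  CI, rank AUC with DeLong interval and Youden cut-off.
* The published validation cross-tabulations of the assay ship as CSV
  fixtures (`validation_tables()`).

## Worked example

Simulate a PR3-positive serum, analyze the well, calibrate a master curve
from a simulated dilution series of a 640 IU/mL reference serum, and
quantify:

```r
library(cytobead)

spec <- sample_spec(pr3_conc = 25, mpo_conc = 2, pattern = "C", titer = 320)
well <- render_sample(spec, simulation_config(rng_seed = 42))
readout <- analyze_well(well$images)
readout
#> sample_readout: PR3 MFI 2671.0, MPO MFI 509.2, cell MFI 299.3, pattern C
#>   beads: PR3 25, MPO 25, REF 25; cells: 30

dil <- 20 * 2^(0:7)                                  # 1/20 ... 1/2560
series <- render_dilution_series(
  sample_spec(pr3_conc = 32, mpo_conc = 32, pattern = "C", titer = 640),
  dil, simulation_config(rng_seed = 7))
std <- data.frame(
  concentration = 640 / dil,
  mfi = sapply(series, function(s) analyze_well(s$images)$pr3_mfi))
curve <- fit_5pl(std, lot_id = "demo-lot")
curve
#> 5PL curve [lot demo-lot]
#>   A = 70.9599  B = 1.20343  C = 9.88146  D = 3524.98  G = 0.99427
#>   valid range: 0.25 - 32 IU/mL

conc <- invert_5pl(curve, readout$pr3_mfi)
sprintf("%.1f IU/mL -> %s", conc, apply_cutoff(conc, "PR3"))
#> "25.1 IU/mL -> positive"
```

The measured MFIs sit below the generator's true amplitudes (the point
spread function attenuates the 2-px halo), but because the master curve is
fitted to *measured* standards the attenuation cancels: the simulated
25 IU/mL serum reads back at 25.1 IU/mL and is called positive against
the 0.9 IU/mL cut-off. The `pattern C` call comes from a majority vote
over the 30 detected cells (cytoplasm/rim ratio ≥ 1.5 with granular
texture).

Agreement statistics on the packaged validation tables:

```r
vt <- validation_tables()
cohens_kappa(vt$pr3)
#> kappa = 0.775 (95% CI 0.710-0.839), n = 592
weighted_kappa(collapse_titer_table(vt$titer))
#> weighted kappa (quadratic) = 0.985 (95% CI 0.980-0.991), n = 592
```

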