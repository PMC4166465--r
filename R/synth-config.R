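#' Built-in "true" dose-response curves of the simulator
#'
#' The generator drives all signal amplitudes from two fixed monotone 5PL
#' curves so that every simulated quantity has a known ground truth.
#'
#' `true_bead_curve()` maps analyte concentration (IU/mL) to the green halo
#' amplitude on antigen-coated beads: floor 100 a.u. at zero dose,
#' saturation 5000 a.u., `C = 10` IU/mL, `B = 1.2`, `G = 1`.
#'
#' `true_cell_curve()` maps the dimensionless staining strength
#' `titer / dilution` to the cell staining amplitude: floor 0, saturation
#' 4000 a.u., `C = 250`, `B = 1`, `G = 1`.  By construction the amplitude at
#' the endpoint dilution (strength 1) is ~16 a.u., of the order of the
#' detection threshold, so a serum titrates out where its titer says it
#' should.
#'
#' @return A [fivepl_curve()].
#' @export
true_bead_curve <- function() {
  fivepl_curve(A = 100, B = 1.2, C = 10, D = 5000, G = 1,
               valid_range = c(0.1, 1000), lot_id = "synthetic-truth")
}

#' @rdname true_bead_curve
#' @export
true_cell_curve <- function() {
  fivepl_curve(A = 0, B = 1, C = 250, D = 4000, G = 1,
               valid_range = c(0.1, 1000), lot_id = "synthetic-truth")
}

#' Simulation configuration for synthetic wells
#'
#' Bundles the optical, geometric and noise parameters of the synthetic
#' microscope.  Defaults place a 40x-objective-like field: 0.25 um/pixel on
#' a 1024 x 1024 sensor, so the 9 um analyte beads span ~36 pixels.
#'
#' @param pixel_scale Pixel size in um/pixel (> 0).
#' @param field_size Integer c(height, width) of the field in pixels.
#' @param n_cells Number of neutrophil-like cells to place.
#' @param n_beads_per_class Number of beads per population (PR3, MPO, REF).
#' @param bead_diameters Named numeric, bead diameters in um; must satisfy
#'   PR3 < REF < MPO (defaults 9, 12, 15).
#' @param psf_sigma Gaussian blur sigma in um emulating the point-spread
#'   function (0 disables blur).
#' @param read_noise_sd Gaussian read noise SD in intensity units (0
#'   disables).
#' @param shot_noise_gain Poisson shot-noise gain in intensity units per
#'   photo-electron (0 disables shot noise).
#' @param background_level Constant background offset added to every plane.
#' @param rng_seed Integer seed; identical (spec, config) pairs render
#'   bit-identical wells.
#' @param bead_curve,cell_curve The true dose-response curves
#'   ([true_bead_curve()], [true_cell_curve()]).
#' @param red_bead_amplitude RED-channel amplitude of the analyte bead body.
#' @param ref_bead_amplitude GREEN-channel amplitude of the solid reference
#'   beads.
#' @param dapi_amplitude DAPI amplitude of the nucleus.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(pixel_scale = 0.25,
                              field_size = c(1024L, 1024L),
                              n_cells = 30L,
                              n_beads_per_class = 25L,
                              bead_diameters = c(PR3 = 9, REF = 12, MPO = 15),
                              psf_sigma = 0.3,
                              read_noise_sd = 2,
                              shot_noise_gain = 1,
                              background_level = 20,
                              rng_seed = 1L,
                              bead_curve = true_bead_curve(),
                              cell_curve = true_cell_curve(),
                              red_bead_amplitude = 3000,
                              ref_bead_amplitude = 2500,
                              dapi_amplitude = 1500) {
  stopifnot(is.numeric(pixel_scale), length(pixel_scale) == 1L,
            length(field_size) == 2L,
            all(c("PR3", "REF", "MPO") %in% names(bead_diameters)),
            inherits(bead_curve, "fivepl_curve"),
            inherits(cell_curve, "fivepl_curve"))
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (any(field_size < 1)) stop("field_size must be positive")
  d <- bead_diameters
  if (!(d[["PR3"]] < d[["REF"]] && d[["REF"]] < d[["MPO"]]))
    stop("bead diameters must be strictly ordered PR3 < REF < MPO")
  if (psf_sigma < 0 || read_noise_sd < 0 || shot_noise_gain < 0 ||
      background_level < 0)
    stop("noise parameters must be >= 0")
  structure(list(
    pixel_scale = pixel_scale,
    field_size = as.integer(field_size),
    n_cells = as.integer(n_cells),
    n_beads_per_class = as.integer(n_beads_per_class),
    bead_diameters = d,
    psf_sigma = psf_sigma,
    read_noise_sd = read_noise_sd,
    shot_noise_gain = shot_noise_gain,
    background_level = background_level,
    rng_seed = as.integer(rng_seed),
    bead_curve = bead_curve,
    cell_curve = cell_curve,
    red_bead_amplitude = red_bead_amplitude,
    ref_bead_amplitude = ref_bead_amplitude,
    dapi_amplitude = dapi_amplitude),
    class = "simulation_config")
}

#' Sample specification for one synthetic well
#'
#' @param pr3_conc,mpo_conc Analyte concentrations in IU/mL (>= 0), defined
#'   at the sample's screening dilution.
#' @param pattern IIF staining pattern: `"C"` (cytoplasmic-granular), `"P"`
#'   (perinuclear rim) or `"NEGATIVE"`.
#' @param titer Classical reciprocal endpoint titer on [titer_ladder()], or
#'   `NA` for a negative sample (a `NEGATIVE` pattern forces `NA`).
#' @param dilution Reciprocal screening dilution (default 20).
#' @return A list of class `sample_spec`.
#' @export
sample_spec <- function(pr3_conc = 0, mpo_conc = 0,
                        pattern = c("NEGATIVE", "C", "P"),
                        titer = NA_real_, dilution = 20) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(pr3_conc), is.numeric(mpo_conc), dilution > 0)
  if (pr3_conc < 0 || mpo_conc < 0) stop("concentrations must be >= 0")
  if (pattern == "NEGATIVE" && !is.na(titer))
    stop("a NEGATIVE pattern implies no titer")
  if (!is.na(titer) && !(titer %in% titer_ladder()))
    stop("titer must lie on the titer ladder")
  structure(list(pr3_conc = pr3_conc, mpo_conc = mpo_conc, pattern = pattern,
                 titer = titer, dilution = dilution),
            class = "sample_spec")
}
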