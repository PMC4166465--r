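#' Write / read a well as a multi-page TIFF with a JSON sidecar
#'
#' One well is stored as a three-page lossless-compressed TIFF (pages DAPI,
#' GREEN, RED; 16-bit, intensities rounded to integer counts) plus a JSON
#' sidecar `<path>.json` carrying the pixel scale and, when available, the
#' ground truth of the synthetic generator.
#'
#' @param img An [image_set()].
#' @param path Output TIFF path.
#' @param truth Optional ground-truth list from [render_sample()].
#' @return `write_well_tiff()` returns `path` invisibly; `read_well_tiff()`
#'   returns a list with `images` (an [image_set()]) and `truth` (or
#'   `NULL`).
#' @export
write_well_tiff <- function(img, path, truth = NULL) {
  stopifnot(inherits(img, "image_set"))
  planes <- lapply(img[c("dapi", "green", "red")],
                   function(p) pmin(pmax(round(p), 0), 65535) / 65535)
  tiff::writeTIFF(unname(planes), path, bits.per.sample = 16L,
                  compression = "deflate")
  sidecar <- list(pixel_scale = img$pixel_scale, pages = c("dapi", "green", "red"))
  if (!is.null(truth)) {
    sidecar$truth <- list(
      beads = truth$beads, cells = truth$cells,
      spec = unclass(truth$spec))
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_well_tiff
#' @export
read_well_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop("expected a 3-page TIFF (DAPI, GREEN, RED)")
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing pixel-scale sidecar: ", sidecar_path)
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * 65535
  })
  truth <- sidecar$truth
  if (!is.null(truth) && !is.null(truth$spec)) {
    s <- truth$spec
    truth$spec <- sample_spec(
      pr3_conc = s$pr3_conc, mpo_conc = s$mpo_conc, pattern = s$pattern,
      titer = if (is.null(s$titer)) NA_real_ else s$titer,
      dilution = s$dilution)
  }
  list(images = image_set(planes[[1]], planes[[2]], planes[[3]],
                          pixel_scale = sidecar$pixel_scale),
       truth = truth)
}

#' Write / read a sample readout as JSON
#'
#' @param readout A `sample_readout` from [summarize_sample()].
#' @param path Output JSON path.
#' @return `write_readout_json()` returns `path` invisibly;
#'   `read_readout_json()` returns the `sample_readout`.
#' @export
write_readout_json <- function(readout, path) {
  stopifnot(inherits(readout, "sample_readout"))
  obj <- unclass(readout)
  obj$n_beads <- as.list(obj$n_beads)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_readout_json
#' @export
read_readout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$n_beads <- unlist(obj$n_beads)
  structure(obj, class = "sample_readout")
}

#' Published validation tables of the assay
#'
#' The printed cross-tabulations from the assay's clinical validation:
#' the PR3-ANCA 2x2 table (ELISA vs microbead immunoassay calls over 592
#' sera) and the 10x10 classical-vs-automated endpoint-titer frequency
#' table over the same sera.  These ship with the package as CSV fixtures
#' and feed the agreement statistics.
#'
#' @return A list with [contingency_table()] elements `pr3` (2x2, rows =
#'   ELISA, columns = microbead assay) and `titer` (10x10, rows = classical
#'   serial-dilution titer, columns = automated single-dilution titer).
#' @export
validation_tables <- function() {
  dir <- system.file("extdata", package = "cytobead", mustWork = TRUE)
  list(
    pr3 = read_table_csv(file.path(dir, "anca_pr3_elisa_vs_mia_2x2.csv")),
    titer = read_table_csv(file.path(dir,
                                     "anca_titer_classical_vs_automated_10x10.csv")))
}
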