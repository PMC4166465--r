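#' Co-registered three-plane fluorescence image of one well
#'
#' @param dapi,green,red Equal-sized 2D non-negative intensity matrices
#'   (DAPI nuclear stain, FITC/green antibody signal, red bead-ID channel).
#' @param pixel_scale Pixel size in um/pixel (> 0).
#' @return A list of class `image_set`.
#' @export
image_set <- function(dapi, green, red, pixel_scale) {
  stopifnot(is.matrix(dapi), is.matrix(green), is.matrix(red))
  if (!all(dim(dapi) == dim(green)) || !all(dim(dapi) == dim(red)))
    stop("all planes must have identical dimensions")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be > 0")
  structure(list(dapi = dapi, green = green, red = red,
                 pixel_scale = pixel_scale),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image_set: %d x %d px at %.3g um/px (DAPI, GREEN, RED)\n",
              nrow(x$dapi), ncol(x$dapi), x$pixel_scale))
  invisible(x)
}

# structured condition helper
cb_stop <- function(class, message, ...) {
  stop(structure(class = c(class, "cytobead_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

# robust background statistics of a plane (objects are sparse, so the
# global median/MAD estimate the background)
bg_stats <- function(plane) {
  list(median = stats::median(plane), mad = stats::mad(plane))
}

# global foreground threshold: median + 5 MAD, falling back to a fraction of
# the dynamic range on noiseless planes (MAD = 0)
fg_threshold <- function(plane, bg = bg_stats(plane)) {
  rng <- max(plane) - bg$median
  if (rng <= .Machine$double.eps) return(Inf)
  if (bg$mad > 0) min(bg$median + 5 * bg$mad, bg$median + 0.5 * rng)
  else bg$median + 0.25 * rng
}

# Per-object half-max refinement: re-threshold the object at background +
# half its peak amplitude so the measured radius of a blurred disk sits at
# the true edge.  Returns the refined logical mask (same dims as crop).
halfmax_mask <- function(crop, coarse, bg_median) {
  amp <- stats::quantile(crop[coarse], 0.9, names = FALSE)
  m <- crop > bg_median + 0.5 * (amp - bg_median)
  lab <- EBImage::bwlabel(m)
  # keep the component overlapping the coarse mask most
  ids <- lab[coarse & lab > 0]
  if (length(ids) == 0L) return(coarse)
  keep <- as.integer(names(which.max(table(ids))))
  lab == keep
}

# shape features of a logical mask: area (px), centroid (local), circularity
mask_features <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  area <- nrow(idx)
  fs <- EBImage::computeFeatures.shape(matrix(as.integer(m), nrow(m)))
  per <- fs[1, "s.perimeter"]
  circ <- if (is.finite(per) && per > 0) min(1, 4 * pi * area / per^2) else 1
  list(area = area, cy = mean(idx[, 1]), cx = mean(idx[, 2]),
       circularity = circ)
}

# iterate over labelled objects of a mask, calling fun(crop_mask, rows, cols)
# on a padded bounding box; returns list of fun results
for_each_object <- function(mask, pad, fun) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  out <- vector("list", n)
  if (n == 0L) return(out)
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  for (k in seq_len(n)) {
    sel <- idx[ids == k, , drop = FALSE]
    rows <- max(1L, min(sel[, 1]) - pad):min(nrow(mask), max(sel[, 1]) + pad)
    cols <- max(1L, min(sel[, 2]) - pad):min(ncol(mask), max(sel[, 2]) + pad)
    om <- lab[rows, cols] == k
    out[[k]] <- fun(om, rows, cols)
  }
  out
}

#' Detect microbead candidates in a well image
#'
#' Analyte-bead candidates are segmented from the RED bead-ID plane,
#' reference-bead candidates from solid (filled, non-annular) objects of the
#' GREEN plane.  Each object is re-thresholded at half its peak amplitude so
#' the equivalent-area diameter of a blurred disk lands on the true edge,
#' then filtered on circularity >= `min_circularity` and diameter within
#' `diameter_range` um.  Green objects are additionally required to be
#' filled (halo rings and cell staining are annular) and to carry no RED or
#' DAPI signal.  Blank planes yield an empty result, not an error.
#'
#' @param img An [image_set()].
#' @param min_circularity Minimum circularity (`4 pi A / P^2`, capped at 1).
#' @param diameter_range Admissible equivalent-area diameter range in um.
#' @return A data frame with one row per candidate: `x`, `y` (px),
#'   `diameter_um`, `circularity`, `channel` (`"analyte"`/`"reference"`),
#'   `bead_class` (`NA`, set by [classify_beads()]).
#' @export
detect_beads <- function(img, min_circularity = 0.8,
                         diameter_range = c(6, 18)) {
  stopifnot(inherits(img, "image_set"))
  sc <- img$pixel_scale
  res <- list()

  bg_r <- bg_stats(img$red)
  thr_r <- fg_threshold(img$red, bg_r)
  bg_g <- bg_stats(img$green)
  thr_g <- fg_threshold(img$green, bg_g)
  bg_d <- bg_stats(img$dapi)
  thr_d <- fg_threshold(img$dapi, bg_d)

  # --- analyte candidates from RED
  if (is.finite(thr_r)) {
    objs <- for_each_object(img$red > thr_r, pad = 4L, function(om, rows, cols) {
      m <- halfmax_mask(img$red[rows, cols], om, bg_r$median)
      f <- mask_features(m)
      data.frame(x = f$cx + cols[1] - 1, y = f$cy + rows[1] - 1,
                 diameter_um = 2 * sqrt(f$area / pi) * sc,
                 circularity = f$circularity, channel = "analyte")
    })
    res <- c(res, objs)
  }

  # --- reference candidates from solid GREEN disks
  if (is.finite(thr_g)) {
    objs <- for_each_object(img$green > thr_g, pad = 4L,
                            function(om, rows, cols) {
      filled <- as.matrix(EBImage::fillHull(om)) > 0
      fill_ratio <- sum(om) / sum(filled)
      if (fill_ratio < 0.85) return(NULL)
      crop <- img$green[rows, cols]
      m <- halfmax_mask(crop, om, bg_g$median)
      m <- as.matrix(EBImage::fillHull(m)) > 0
      f <- mask_features(m)
      # reject anything carrying red (analyte bead) or DAPI (cell) signal
      if (mean(img$red[rows, cols][m]) > max(thr_r, bg_r$median + 1e-9) ||
          mean(img$dapi[rows, cols][m]) > max(thr_d, bg_d$median + 1e-9))
        return(NULL)
      data.frame(x = f$cx + cols[1] - 1, y = f$cy + rows[1] - 1,
                 diameter_um = 2 * sqrt(f$area / pi) * sc,
                 circularity = f$circularity, channel = "reference")
    })
    res <- c(res, objs)
  }

  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      diameter_um = numeric(0), circularity = numeric(0),
                      channel = character(0), bead_class = character(0)))
  out <- do.call(rbind, res)
  out <- out[out$circularity >= min_circularity &
               out$diameter_um >= diameter_range[1] &
               out$diameter_um <= diameter_range[2], , drop = FALSE]
  out$bead_class <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify analyte beads by size against the reference population
#'
#' The 12 um solid reference beads calibrate the size scale: a scale factor
#' `median(reference diameter) / 12` corrects all analyte diameters, which
#' are then demultiplexed as PR3 when the corrected diameter is below
#' `thresholds[1]` (default 10.5 um) and MPO when above `thresholds[2]`
#' (default 13.5 um).  Candidates falling in the dead zone between the
#' thresholds are excluded.
#'
#' @param beads A [detect_beads()] result.
#' @param ref_diameter_um Nominal reference-bead diameter (12 um).
#' @param thresholds Lower/upper corrected-diameter thresholds in um.
#' @return The bead data frame with `bead_class` set (`PR3`, `MPO`, `REF`)
#'   and a `diameter_corrected` column; dead-zone candidates are dropped
#'   (their count is kept in attribute `n_unclassified`).
#' @export
classify_beads <- function(beads, ref_diameter_um = 12,
                           thresholds = c(10.5, 13.5)) {
  stopifnot(is.data.frame(beads))
  ref <- beads$channel == "reference"
  if (sum(ref) < 3L)
    cb_stop("cytobead_missing_reference",
            sprintf(paste0("size calibration impossible: %d reference bead(s)",
                           " found, need >= 3"), sum(ref)))
  scale_factor <- stats::median(beads$diameter_um[ref]) / ref_diameter_um
  beads$diameter_corrected <- beads$diameter_um / scale_factor
  beads$bead_class[ref] <- "REF"
  ana <- which(!ref)
  d <- beads$diameter_corrected[ana]
  cls <- rep(NA_character_, length(ana))
  cls[d < thresholds[1]] <- "PR3"
  cls[d > thresholds[2]] <- "MPO"
  beads$bead_class[ana] <- cls
  n_un <- sum(is.na(beads$bead_class))
  out <- beads[!is.na(beads$bead_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unclassified") <- n_un
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Measure the green surface halo of one bead
#'
#' The halo MFI is the mean GREEN intensity in the annulus `[r, r + 2 px]`
#' at the bead rim minus the mean in a local background annulus
#' `[r + 4, r + 6 px]`, floored at zero.  Beads whose background annulus
#' leaves the image are skipped with a warning (`NA` returned).
#'
#' @param img An [image_set()].
#' @param x,y Bead center in pixels.
#' @param diameter_um Bead diameter in um (uncorrected, as rendered).
#' @return The background-subtracted halo MFI (a.u.), or `NA` at the
#'   border.
#' @export
measure_halo <- function(img, x, y, diameter_um) {
  stopifnot(inherits(img, "image_set"))
  r <- diameter_um / 2 / img$pixel_scale
  r_out <- r + 6
  h <- nrow(img$green); w <- ncol(img$green)
  if (x - r_out < 1 || x + r_out > w || y - r_out < 1 || y + r_out > h) {
    warning("bead at (", round(x), ", ", round(y),
            ") touches the image border; halo measurement skipped")
    return(NA_real_)
  }
  rows <- floor(y - r_out):ceiling(y + r_out)
  cols <- floor(x - r_out):ceiling(x + r_out)
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  crop <- img$green[rows, cols]
  sig <- crop[d2 > r^2 & d2 <= (r + 2)^2]
  bgv <- crop[d2 > (r + 4)^2 & d2 <= (r + 6)^2]
  max(0, mean(sig) - mean(bgv))
}

#' Measure halos for all classified analyte beads
#'
#' @param img An [image_set()].
#' @param beads A [classify_beads()] result.
#' @return `beads` with a `halo_mfi` column (`NA` for reference beads and
#'   border-skipped beads).
#' @export
measure_halos <- function(img, beads) {
  beads$halo_mfi <- NA_real_
  ana <- which(beads$bead_class %in% c("PR3", "MPO"))
  for (i in ana)
    beads$halo_mfi[i] <- measure_halo(img, beads$x[i], beads$y[i],
                                      beads$diameter_um[i])
  beads
}

#' Detect and measure neutrophil-like cells
#'
#' Nuclei are segmented from the DAPI plane by a global threshold followed
#' by a tolerance-limited watershed split of the distance map (lobulated
#' nuclei stay whole, touching nuclei separate).  For each nucleus a
#' perinuclear rim band (dilation by `rim_width_um` minus the nucleus) and a
#' cytoplasmic band (dilation by `cyto_width_um` minus rim and nucleus) are
#' constructed, and the GREEN plane is summarized per band:
#' background-subtracted rim and cytoplasm MFIs (floored at 0) and the
#' cytoplasmic granularity (coefficient of variation).
#'
#' The GREEN positivity threshold (background median + 3 MAD, expressed
#' after background subtraction as 3 MAD) is attached as attribute
#' `positivity_threshold` for [classify_pattern()].
#'
#' @param img An [image_set()].
#' @param rim_width_um Width of the perinuclear band (default 1 um).
#' @param cyto_width_um Outer reach of the cytoplasmic band (default 4 um).
#' @param min_nucleus_area_um2 Minimum nucleus area; smaller DAPI specks are
#'   discarded.
#' @param split_tolerance_um Watershed merge tolerance (object-depth units
#'   of the distance map, in um).
#' @return A data frame with one row per cell: `x`, `y`, `nucleus_area_um2`,
#'   `rim_mfi`, `cytoplasm_mfi`, `granularity`; attributes
#'   `positivity_threshold` and `background`.
#' @export
detect_cells <- function(img, rim_width_um = 1, cyto_width_um = 4,
                         min_nucleus_area_um2 = 8, split_tolerance_um = 1.5) {
  stopifnot(inherits(img, "image_set"))
  sc <- img$pixel_scale
  bg_d <- bg_stats(img$dapi)
  thr_d <- fg_threshold(img$dapi, bg_d)
  bg_g <- bg_stats(img$green)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      nucleus_area_um2 = numeric(0), rim_mfi = numeric(0),
                      cytoplasm_mfi = numeric(0), granularity = numeric(0))
  attr(empty, "positivity_threshold") <- 3 * bg_g$mad
  attr(empty, "background") <- bg_g$median
  if (!is.finite(thr_d)) return(empty)

  mask <- img$dapi > thr_d
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = split_tolerance_um / sc, ext = 1)
  lab <- as.matrix(lab)
  n <- max(lab)
  if (n == 0L) return(empty)

  pad <- ceiling((cyto_width_um + 1) / sc)
  rows_list <- list()
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  for (k in seq_len(n)) {
    sel <- idx[ids == k, , drop = FALSE]
    if (nrow(sel) * sc^2 < min_nucleus_area_um2) next
    rows <- max(1L, min(sel[, 1]) - pad):min(nrow(lab), max(sel[, 1]) + pad)
    cols <- max(1L, min(sel[, 2]) - pad):min(ncol(lab), max(sel[, 2]) + pad)
    nm <- lab[rows, cols] == k
    # refine the nucleus edge at half-max so the blur skirt does not
    # inflate the nucleus and shift the rim band onto the cytoplasm
    nm <- halfmax_mask(img$dapi[rows, cols], nm, bg_d$median)
    area_um2 <- sum(nm) * sc^2
    if (area_um2 < min_nucleus_area_um2) next
    nidx <- which(nm, arr.ind = TRUE)
    dist <- as.matrix(EBImage::distmap(!nm))
    rim <- dist > 0 & dist <= rim_width_um / sc
    cyto <- dist > rim_width_um / sc & dist <= cyto_width_um / sc
    g <- img$green[rows, cols]
    rim_mfi <- max(0, mean(g[rim]) - bg_g$median)
    cyto_v <- g[cyto]
    cyto_mfi <- max(0, mean(cyto_v) - bg_g$median)
    gran <- if (mean(cyto_v) > 0) stats::sd(cyto_v) / mean(cyto_v) else 0
    rows_list[[length(rows_list) + 1L]] <- data.frame(
      x = mean(nidx[, 2]) + cols[1] - 1, y = mean(nidx[, 1]) + rows[1] - 1,
      nucleus_area_um2 = area_um2, rim_mfi = rim_mfi,
      cytoplasm_mfi = cyto_mfi, granularity = gran)
  }
  if (length(rows_list) == 0L) return(empty)
  out <- do.call(rbind, rows_list)
  rownames(out) <- NULL
  attr(out, "positivity_threshold") <- 3 * bg_g$mad
  attr(out, "background") <- bg_g$median
  out
}

#' Call the IIF staining pattern of a sample
#'
#' Per cell: `NEGATIVE` when neither band MFI reaches the positivity
#' threshold; otherwise `P` when the rim dominates
#' (`rim / cytoplasm >= ratio`), `C` when the cytoplasm dominates
#' (`cytoplasm / rim >= ratio`) and the granularity exceeds
#' `granularity_threshold`; cells in between stay uncalled and do not vote.
#' The sample call is the majority vote over the positive calls, `NEGATIVE`
#' when fewer than `min_positive` cells are positive (ties go to `C`).
#'
#' @param cells A [detect_cells()] result.
#' @param ratio Band dominance ratio (default 1.5).
#' @param granularity_threshold Minimum cytoplasmic CV for a `C` call.
#' @param min_positive Minimum number of positive cells for a positive
#'   sample (default 20).
#' @param threshold Positivity threshold on the background-subtracted band
#'   MFIs; defaults to the `positivity_threshold` attribute of `cells`.
#' @return `"P"`, `"C"` or `"NEGATIVE"`, with per-cell calls in attribute
#'   `cell_calls`.
#' @export
classify_pattern <- function(cells, ratio = 1.5, granularity_threshold = 0.3,
                             min_positive = 20,
                             threshold = attr(cells, "positivity_threshold")) {
  stopifnot(is.data.frame(cells))
  if (is.null(threshold)) stop("no positivity threshold available")
  if (nrow(cells) == 0L) return(structure("NEGATIVE", cell_calls = character(0)))
  pos <- pmax(cells$rim_mfi, cells$cytoplasm_mfi) >= threshold
  calls <- rep(NA_character_, nrow(cells))
  calls[!pos] <- "NEGATIVE"
  rp <- cells$rim_mfi / pmax(cells$cytoplasm_mfi, .Machine$double.eps)
  calls[pos & rp >= ratio] <- "P"
  calls[pos & rp <= 1 / ratio &
          cells$granularity > granularity_threshold] <- "C"
  n_pos <- sum(pos)
  sample_call <- if (n_pos < min_positive) "NEGATIVE" else {
    votes <- c(C = sum(calls == "C", na.rm = TRUE),
               P = sum(calls == "P", na.rm = TRUE))
    if (sum(votes) == 0L) "NEGATIVE" else names(votes)[which.max(votes)]
  }
  structure(sample_call, cell_calls = calls, n_positive = n_pos)
}

#' Aggregate a well into a sample readout
#'
#' Averages halo MFIs per analyte bead class, counts objects, and attaches
#' the IIF pattern call and the cell MFI (mean over positive cells of the
#' dominant band).  A readout is only issued when the well contains at
#' least `min_beads` analyte beads and `min_cells` cells; otherwise an
#' explicit `cytobead_insufficient_objects` error carrying the observed
#' counts is raised.  An analyte class with no measurable bead raises
#' `cytobead_missing_class`.
#'
#' @param beads A [measure_halos()] result (classified, with `halo_mfi`).
#' @param cells A [detect_cells()] result.
#' @param min_beads Minimum analyte (PR3 + MPO) bead count (default 50).
#' @param min_cells Minimum cell count (default 20).
#' @param ... Passed to [classify_pattern()].
#' @return A list of class `sample_readout`: `pr3_mfi`, `mpo_mfi`,
#'   `cell_mfi`, `n_beads` (named counts), `n_cells`, `pattern`.
#' @export
summarize_sample <- function(beads, cells, min_beads = 50, min_cells = 20,
                             ...) {
  stopifnot(is.data.frame(beads), is.data.frame(cells))
  if (!"halo_mfi" %in% names(beads))
    stop("beads must carry halo_mfi; run measure_halos() first")
  n_beads <- c(PR3 = sum(beads$bead_class == "PR3"),
               MPO = sum(beads$bead_class == "MPO"),
               REF = sum(beads$bead_class == "REF"))
  n_ana <- n_beads[["PR3"]] + n_beads[["MPO"]]
  n_cells <- nrow(cells)
  if (n_ana < min_beads || n_cells < min_cells)
    cb_stop("cytobead_insufficient_objects",
            sprintf(paste0("insufficient objects for a valid readout: ",
                           "%d analyte beads (need >= %d), %d cells ",
                           "(need >= %d)"), n_ana, min_beads, n_cells,
                    min_cells),
            n_beads = n_ana, n_cells = n_cells)
  for (cl in c("PR3", "MPO"))
    if (sum(beads$bead_class == cl & !is.na(beads$halo_mfi)) == 0L)
      cb_stop("cytobead_missing_class",
              paste0("no measurable ", cl, " bead in the well"))
  pattern <- classify_pattern(cells, ...)
  calls <- attr(pattern, "cell_calls")
  pos <- !is.na(calls) & calls != "NEGATIVE"
  cell_mfi <- if (any(pos))
    mean(pmax(cells$rim_mfi, cells$cytoplasm_mfi)[pos]) else 0
  structure(list(
    pr3_mfi = mean(beads$halo_mfi[beads$bead_class == "PR3"], na.rm = TRUE),
    mpo_mfi = mean(beads$halo_mfi[beads$bead_class == "MPO"], na.rm = TRUE),
    cell_mfi = cell_mfi,
    n_beads = n_beads, n_cells = n_cells,
    pattern = as.character(pattern)),
    class = "sample_readout")
}

#' @export
print.sample_readout <- function(x, ...) {
  cat(sprintf(paste0("sample_readout: PR3 MFI %.1f, MPO MFI %.1f, ",
                     "cell MFI %.1f, pattern %s\n"),
              x$pr3_mfi, x$mpo_mfi, x$cell_mfi, x$pattern))
  cat(sprintf("  beads: PR3 %d, MPO %d, REF %d; cells: %d\n",
              x$n_beads[["PR3"]], x$n_beads[["MPO"]], x$n_beads[["REF"]],
              x$n_cells))
  invisible(x)
}

#' Cell-compartment readout of a well
#'
#' Detects cells, calls the IIF pattern and summarizes the cell MFI (mean
#' over positive cells of the dominant band, the quantity the
#' single-dilution titer model consumes).  This is the cell-only half of
#' [analyze_well()], useful for wells imaged for pattern and titer work
#' where no bead readout is needed.
#'
#' @param img An [image_set()].
#' @param ... Passed to [classify_pattern()].
#' @return A list: `pattern`, `cell_mfi`, `n_cells`, `n_positive`.
#' @export
well_pattern_readout <- function(img, ...) {
  cells <- detect_cells(img)
  pattern <- classify_pattern(cells, ...)
  calls <- attr(pattern, "cell_calls")
  pos <- !is.na(calls) & calls != "NEGATIVE"
  list(pattern = as.character(pattern),
       cell_mfi = if (any(pos))
         mean(pmax(cells$rim_mfi, cells$cytoplasm_mfi)[pos]) else 0,
       n_cells = nrow(cells),
       n_positive = attr(pattern, "n_positive"))
}

#' Analyze one well end to end
#'
#' Convenience pipeline: [detect_beads()] -> [classify_beads()] ->
#' [measure_halos()] -> [detect_cells()] -> [summarize_sample()].
#'
#' @param img An [image_set()].
#' @param min_beads,min_cells Validity minima, see [summarize_sample()].
#' @param ... Passed to [classify_pattern()] via [summarize_sample()].
#' @return A `sample_readout`.
#' @export
analyze_well <- function(img, min_beads = 50, min_cells = 20, ...) {
  beads <- classify_beads(detect_beads(img))
  beads <- measure_halos(img, beads)
  cells <- detect_cells(img)
  summarize_sample(beads, cells, min_beads = min_beads,
                   min_cells = min_cells, ...)
}
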