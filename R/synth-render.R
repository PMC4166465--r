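# Synthetic CytoBead well renderer.
#
# All geometry is drawn into local bounding boxes, additively, in photon-like
# units; background, shot noise (Poisson), read noise (Gaussian) and PSF blur
# (Gaussian) are applied per plane afterwards, in that order.

# evaluate an expression under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sequential rejection placement of circular exclusion zones.
# existing: data.frame(x, y, excl). Returns data.frame(x, y, excl).
place_centers <- function(n, excl, h, w, existing = NULL,
                          max_tries = 4000L) {
  excl <- rep_len(excl, n)
  xs <- numeric(n); ys <- numeric(n)
  ex <- if (is.null(existing)) numeric(0) else existing$x
  ey <- if (is.null(existing)) numeric(0) else existing$y
  ee <- if (is.null(existing)) numeric(0) else existing$excl
  for (i in seq_len(n)) {
    r <- excl[i]
    if (2 * r >= min(h, w))
      stop("field too small to place an object with exclusion radius ", r)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r + 1, w - r)
      y <- stats::runif(1, r + 1, h - r)
      if (length(ex) == 0L ||
          all((x - ex)^2 + (y - ey)^2 >= (r + ee)^2)) {
        xs[i] <- x; ys[i] <- y
        ex <- c(ex, x); ey <- c(ey, y); ee <- c(ee, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("object placement failed after ", max_tries,
           " tries; field too crowded for the requested object counts")
  }
  data.frame(x = xs, y = ys, excl = excl)
}

# linear indices of an annulus (cx = column, cy = row, radii in pixels);
# the caller adds amplitudes in place to avoid copying the full plane
annulus_idx <- function(h, w, cx, cy, r_in, r_out) {
  rows <- max(1L, floor(cy - r_out - 1)):min(h, ceiling(cy + r_out + 1))
  cols <- max(1L, floor(cx - r_out - 1)):min(w, ceiling(cx + r_out + 1))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  m <- d2 > r_in^2 & d2 <= r_out^2
  as.vector(outer(rows, (cols - 1L) * h, "+"))[m]
}

disk_idx <- function(h, w, cx, cy, r) annulus_idx(h, w, cx, cy, -1, r)

# lobulated nucleus mask in a local window: 2-4 overlapping ellipses
nucleus_mask <- function(win, cx, cy, scale) {
  n_lobes <- sample(2:4, 1)
  m <- matrix(FALSE, win, win)
  rows <- seq_len(win); cols <- seq_len(win)
  for (k in seq_len(n_lobes)) {
    th <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0, 2.2) / scale
    ox <- cx + off * cos(th); oy <- cy + off * sin(th)
    a <- stats::runif(1, 1.8, 3.2) / scale
    b <- stats::runif(1, 1.4, 2.6) / scale
    phi <- stats::runif(1, 0, pi)
    dx <- outer(rep(1, win), cols - ox)
    dy <- outer(rows - oy, rep(1, win))
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    m <- m | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  m
}

apply_camera <- function(plane, cfg) {
  plane <- plane + cfg$background_level
  if (cfg$shot_noise_gain > 0) {
    g <- cfg$shot_noise_gain
    plane[] <- stats::rpois(length(plane), pmax(plane, 0) / g) * g
  }
  if (cfg$read_noise_sd > 0)
    plane <- plane + stats::rnorm(length(plane), 0, cfg$read_noise_sd)
  if (cfg$psf_sigma > 0)
    plane <- as.matrix(EBImage::gblur(plane,
                                      sigma = cfg$psf_sigma / cfg$pixel_scale))
  plane
}

#' Render one synthetic CytoBead well
#'
#' Draws a three-plane field (DAPI, GREEN, RED) for one serum sample under
#' the assay principle: analyte beads carry a red body and a green surface
#' halo whose amplitude follows the built-in true 5PL response of the
#' corresponding analyte concentration; solid green 12 um reference beads
#' anchor the size scale; neutrophil-like cells show a lobulated DAPI
#' nucleus and, for positive sera, either granular cytoplasmic (C) or
#' perinuclear rim (P) green staining whose amplitude follows the true cell
#' response at strength `titer / dilution`.  Shot noise, read noise and PSF
#' blur are applied per plane.
#'
#' @param spec A [sample_spec()].
#' @param cfg A [simulation_config()].
#' @return A list with elements `images` (an [image_set()]) and `truth`
#'   (list: `beads` data frame with `x`, `y`, `diameter_um`, `class`,
#'   `halo_amplitude`; `cells` data frame with `x`, `y`, `pattern`,
#'   `amplitude`; `spec`).
#' @export
render_sample <- function(spec, cfg = simulation_config()) {
  stopifnot(inherits(spec, "sample_spec"), inherits(cfg, "simulation_config"))
  h <- cfg$field_size[1]; w <- cfg$field_size[2]
  sc <- cfg$pixel_scale
  px <- function(um) um / sc

  with_seed(cfg$rng_seed, {
    dapi <- matrix(0, h, w); green <- matrix(0, h, w); red <- matrix(0, h, w)

    # ---- layout: cells first (largest exclusion zones), then beads
    cell_excl <- px(8.5)                     # nucleus + cytoplasm + margin
    cells <- if (cfg$n_cells > 0)
      place_centers(cfg$n_cells, cell_excl, h, w) else NULL
    diam <- cfg$bead_diameters
    bead_class <- rep(c("PR3", "MPO", "REF"), each = cfg$n_beads_per_class)
    bead_r <- px(diam[bead_class] / 2)
    beads <- if (length(bead_class) > 0)
      place_centers(length(bead_class), bead_r + px(3), h, w,
                    existing = cells) else NULL

    # ---- cells
    S <- if (spec$pattern == "NEGATIVE" || is.na(spec$titer)) 0 else
      eval_5pl(cfg$cell_curve, spec$titer / spec$dilution)
    cell_truth <- NULL
    if (!is.null(cells)) {
      win <- 2L * ceiling(px(8.5)) + 1L
      half <- (win - 1L) / 2L
      amp_i <- numeric(nrow(cells))
      ncx <- numeric(nrow(cells)); ncy <- numeric(nrow(cells))
      for (i in seq_len(nrow(cells))) {
        cx <- round(cells$x[i]); cy <- round(cells$y[i])
        rows <- (cy - half):(cy + half); cols <- (cx - half):(cx + half)
        lin <- as.vector(outer(rows, (cols - 1L) * h, "+"))
        nm <- nucleus_mask(win, half + 1, half + 1, sc)
        nix <- which(nm, arr.ind = TRUE)
        ncy[i] <- mean(nix[, 1]) + rows[1] - 1   # nucleus centroid, the
        ncx[i] <- mean(nix[, 2]) + cols[1] - 1   # landmark detection sees
        dapi[lin[nm]] <- dapi[lin[nm]] + cfg$dapi_amplitude
        amp_i[i] <- S * exp(stats::rnorm(1, 0, 0.1))   # per-cell brightness
        if (amp_i[i] > 0) {
          dist <- as.matrix(EBImage::distmap(!nm))
          rim <- dist > 0 & dist <= px(1)
          cyto <- dist > px(1) & dist <= px(4)
          g <- matrix(0, win, win)
          if (spec$pattern == "P") {
            g[rim] <- amp_i[i]
            g[cyto] <- 0.15 * amp_i[i]
          } else {                           # C: granular cytoplasm
            g[cyto] <- 0.3 * amp_i[i]
            g[rim] <- 0.25 * amp_i[i]
            idx <- which(cyto)
            if (length(idx) > 0) {
              seeds <- matrix(FALSE, win, win)
              seeds[sample(idx, max(1L, round(0.035 * length(idx))))] <- TRUE
              gran <- EBImage::dilate(seeds, EBImage::makeBrush(5, "disc")) &
                cyto
              g[gran] <- g[gran] + 2 * amp_i[i]
            }
          }
          green[lin] <- green[lin] + as.vector(g)
        }
      }
      cell_truth <- data.frame(x = ncx, y = ncy,
                               pattern = spec$pattern, amplitude = amp_i)
    }

    # ---- beads
    halo <- c(PR3 = eval_5pl(cfg$bead_curve, spec$pr3_conc),
              MPO = eval_5pl(cfg$bead_curve, spec$mpo_conc))
    bead_truth <- NULL
    if (!is.null(beads)) {
      amp <- numeric(nrow(beads))
      for (i in seq_len(nrow(beads))) {
        cl <- bead_class[i]; r <- bead_r[i]
        if (cl == "REF") {
          ii <- disk_idx(h, w, beads$x[i], beads$y[i], r)
          green[ii] <- green[ii] + cfg$ref_bead_amplitude
          amp[i] <- NA_real_
        } else {
          ii <- disk_idx(h, w, beads$x[i], beads$y[i], r)
          red[ii] <- red[ii] + cfg$red_bead_amplitude
          amp[i] <- halo[[cl]]
          # the halo bleeds half a pixel inward and outward of the nominal
          # 2 px rim band, so a measurement annulus anchored on a sub-pixel
          # radius estimate still samples pure halo
          ii <- annulus_idx(h, w, beads$x[i], beads$y[i], r - 0.5, r + 2.5)
          green[ii] <- green[ii] + amp[i]
        }
      }
      bead_truth <- data.frame(x = beads$x, y = beads$y,
                               diameter_um = diam[bead_class],
                               class = bead_class, halo_amplitude = amp,
                               row.names = NULL)
    }

    dapi <- apply_camera(dapi, cfg)
    green <- apply_camera(green, cfg)
    red <- apply_camera(red, cfg)

    list(images = image_set(dapi, green, red, pixel_scale = sc),
         truth = list(beads = bead_truth, cells = cell_truth, spec = spec))
  })
}

#' Render a serial-dilution series of one sample
#'
#' Produces one well per requested reciprocal dilution; sample `k` carries
#' analyte concentrations scaled by `base$dilution / dilutions[k]` (and the
#' cell staining strength `titer / dilutions[k]` scales accordingly).  Well
#' seeds are derived deterministically from `cfg$rng_seed`.
#'
#' @param base A [sample_spec()] defined at its own `dilution`.
#' @param dilutions Positive, strictly increasing reciprocal dilutions.
#' @param cfg A [simulation_config()].
#' @return A list of `render_sample()` results, one per dilution.
#' @export
render_dilution_series <- function(base, dilutions,
                                   cfg = simulation_config()) {
  stopifnot(inherits(base, "sample_spec"))
  if (length(dilutions) == 0L) stop("dilution list must not be empty")
  if (any(dilutions <= 0) || is.unsorted(dilutions, strictly = TRUE))
    stop("dilutions must be positive and strictly increasing")
  lapply(seq_along(dilutions), function(k) {
    f <- base$dilution / dilutions[k]
    spec_k <- sample_spec(pr3_conc = base$pr3_conc * f,
                          mpo_conc = base$mpo_conc * f,
                          pattern = base$pattern, titer = base$titer,
                          dilution = dilutions[k])
    cfg_k <- cfg
    cfg_k$rng_seed <- cfg$rng_seed + k
    render_sample(spec_k, cfg_k)
  })
}

#' Generate a synthetic cohort of wells
#'
#' Draws samples group by group: per-analyte seropositivity is Bernoulli at
#' the requested prevalence, positive concentrations are log-normal around
#' `conc_meanlog`/`conc_sdlog`, the IIF pattern follows the analyte content
#' (PR3-only positive: C; MPO-only: P; double-positive: drawn from
#' `pattern_mix`; negative: NEGATIVE), and positive sera receive an endpoint
#' titer drawn from `titer_dist`.
#'
#' @param group_specs A list of group descriptors, each a list with fields
#'   `label`, `n`, `prev_pr3`, `prev_mpo` (prevalences in `[0, 1]`), and
#'   optionally `pattern_mix` (named probabilities for `C` and `P` in
#'   double positives), `titer_dist` (named probabilities over
#'   [titer_ladder()] rungs), `conc_meanlog`, `conc_sdlog`.
#' @param cfg A [simulation_config()].
#' @param render Render the wells (`TRUE`) or return the drawn
#'   specifications only (`FALSE`), which is cheap and useful for
#'   design checks.
#' @return A list with one element per sample: `label`, `spec`, and (when
#'   rendered) `images` and `truth`.
#' @export
generate_cohort <- function(group_specs, cfg = simulation_config(),
                            render = TRUE) {
  stopifnot(is.list(group_specs))
  for (g in group_specs) {
    stopifnot(!is.null(g$label), !is.null(g$n))
    if (g$n < 0) stop("group size must be >= 0")
    pv <- c(g$prev_pr3, g$prev_mpo)
    if (any(pv < 0 | pv > 1)) stop("prevalences must lie in [0, 1]")
  }
  ladder <- titer_ladder()
  out <- with_seed(cfg$rng_seed, {
    res <- list()
    for (g in group_specs) {
      if (g$n == 0L) next
      mix <- if (is.null(g$pattern_mix)) c(C = 0.5, P = 0.5) else g$pattern_mix
      tdist <- if (is.null(g$titer_dist))
        stats::setNames(c(0, 0.2, 0.2, 0.2, 0.15, 0.1, 0.08, 0.04, 0.02, 0.01),
                        ladder) else g$titer_dist
      ml <- if (is.null(g$conc_meanlog)) log(30) else g$conc_meanlog
      sl <- if (is.null(g$conc_sdlog)) 0.7 else g$conc_sdlog
      for (i in seq_len(g$n)) {
        pr3_pos <- stats::runif(1) < g$prev_pr3
        mpo_pos <- stats::runif(1) < g$prev_mpo
        pattern <- if (pr3_pos && mpo_pos)
          sample(names(mix), 1, prob = mix)
        else if (pr3_pos) "C" else if (mpo_pos) "P" else "NEGATIVE"
        titer <- if (pattern == "NEGATIVE") NA_real_ else
          as.numeric(sample(names(tdist), 1, prob = tdist))
        spec <- sample_spec(
          pr3_conc = if (pr3_pos) stats::rlnorm(1, ml, sl) else 0,
          mpo_conc = if (mpo_pos) stats::rlnorm(1, ml, sl) else 0,
          pattern = pattern, titer = titer)
        res[[length(res) + 1L]] <- list(label = g$label, spec = spec,
                                        seed = cfg$rng_seed + length(res) + 1L)
      }
    }
    res
  })
  if (render) {
    out <- lapply(out, function(s) {
      cfg_i <- cfg
      cfg_i$rng_seed <- s$seed
      r <- render_sample(s$spec, cfg_i)
      c(s, r)
    })
  }
  out
}
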