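#' Five-parameter logistic dose-response curve
#'
#' Constructs a 5PL calibration curve of the form
#' \deqn{y(x) = D + \frac{A - D}{\left(1 + (x/C)^B\right)^G}}
#' where `A` is the asymptote at zero concentration, `D` the asymptote at
#' infinite concentration, `C` an inflection-scale concentration, `B` the
#' slope factor and `G` the asymmetry factor.  The curve is monotone in `x`
#' for any admissible parameter set; it increases when `D > A` (the usual
#' immunoassay orientation) and decreases when `A > D`.
#'
#' @param A Asymptote at zero concentration (arbitrary fluorescence units).
#' @param B Slope factor (dimensionless, non-zero).
#' @param C Inflection-scale concentration (IU/mL, positive).
#' @param D Asymptote at infinite concentration (arbitrary units).
#' @param G Asymmetry factor (dimensionless, positive); `G = 1` recovers the
#'   symmetric 4PL.
#' @param valid_range Length-2 numeric, concentration range covered by the
#'   fitted standards.
#' @param lot_id Character lot identifier carried into the charge
#'   certificate.
#' @return An object of class `fivepl_curve`.
#' @seealso [eval_5pl()], [invert_5pl()], [fit_5pl()],
#'   [recalibrate_two_point()]
#' @export
fivepl_curve <- function(A, B, C, D, G, valid_range = c(NA_real_, NA_real_),
                         lot_id = NA_character_) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(D),
            is.numeric(G), length(valid_range) == 2L)
  if (!is.finite(C) || C <= 0) stop("5PL scale parameter C must be > 0")
  if (!is.finite(B) || B == 0) stop("5PL slope parameter B must be non-zero")
  if (!is.finite(G) || G <= 0) stop("5PL asymmetry parameter G must be > 0")
  if (A == D) stop("5PL asymptotes A and D must differ")
  structure(
    list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
         D = as.numeric(D), G = as.numeric(G),
         valid_range = as.numeric(valid_range), lot_id = lot_id),
    class = "fivepl_curve")
}

#' @export
print.fivepl_curve <- function(x, ...) {
  cat("5PL curve", if (!is.na(x$lot_id)) paste0("[lot ", x$lot_id, "]"), "\n")
  cat(sprintf("  A = %.6g  B = %.6g  C = %.6g  D = %.6g  G = %.6g\n",
              x$A, x$B, x$C, x$D, x$G))
  if (all(is.finite(x$valid_range)))
    cat(sprintf("  valid range: %.4g - %.4g IU/mL\n",
                x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Evaluate a 5PL curve
#'
#' @param curve A [fivepl_curve()].
#' @param x Concentration(s), `>= 0`.  `x = 0` returns the zero-dose
#'   asymptote `A` (for positive slope `B`) without a division error.
#' @return Predicted response(s) in the units of the fitted MFIs.
#' @export
eval_5pl <- function(curve, x) {
  stopifnot(inherits(curve, "fivepl_curve"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  # 0^B = 0 for B > 0 and Inf for B < 0; both limits fall out naturally.
  u <- (x / curve$C)^curve$B
  curve$D + (curve$A - curve$D) / (1 + u)^curve$G
}

#' Invert a 5PL curve (dose interpolation)
#'
#' Back-calculates the concentration producing a given response,
#' \eqn{x = C\,(((A-D)/(y-D))^{1/G} - 1)^{1/B}}.  The response must lie
#' strictly between the two asymptotes; values at or beyond the asymptote on
#' the zero-dose side raise a `cytobead_below_floor` condition and on the
#' saturating side a `cytobead_above_ceiling` condition.
#'
#' @param curve A [fivepl_curve()].
#' @param y Response value(s).
#' @return Concentration(s) in the units of the curve.
#' @export
invert_5pl <- function(curve, y) {
  stopifnot(inherits(curve, "fivepl_curve"), is.numeric(y))
  lo <- min(curve$A, curve$D)
  hi <- max(curve$A, curve$D)
  # which asymptote is the zero-dose one depends on orientation
  floor_side <- if (curve$B > 0) curve$A else curve$D
  bad_lo <- y <= lo
  bad_hi <- y >= hi
  if (any(bad_lo | bad_hi)) {
    off <- y[bad_lo | bad_hi][1]
    at_floor <- (off <= lo) == (floor_side == lo)
    cls <- if (at_floor) "cytobead_below_floor" else "cytobead_above_ceiling"
    stop(structure(class = c(cls, "cytobead_out_of_range", "error",
                             "condition"),
                   list(message = sprintf(
                     "response %.6g outside the open 5PL range (%.6g, %.6g): %s",
                     off, lo, hi,
                     if (at_floor) "below assay floor" else "above assay ceiling"),
                     call = sys.call(-1))))
  }
  curve$C * (((curve$A - curve$D) / (y - curve$D))^(1 / curve$G) - 1)^(1 / curve$B)
}

#' Fit a 5PL master curve to calibration standards
#'
#' Least-squares fit (Levenberg-Marquardt, [minpack.lm::nlsLM()]) of the 5PL
#' response model to standard points, as used to build lot-specific master
#' curves from a dilution series of a reference serum.  Starting values are
#' taken from the data: the asymptotes from the responses at the lowest and
#' highest standard concentrations, `C` from the concentration whose response
#' is nearest the half-range, `B = 1`, `G = 1`.  Up to `restarts` jittered
#' restarts are attempted before giving up.
#'
#' @param standards A data frame with columns `concentration` (IU/mL, > 0)
#'   and `mfi` (positive response); at least 6 distinct concentrations.
#' @param lot_id Optional lot identifier stored on the returned curve.
#' @param weighting `"relative"` (default) weights residuals by `1 / mfi^2`,
#'   the standard choice for the roughly multiplicative error of
#'   fluorescence readouts; `"none"` fits unweighted.
#' @details The optimizer is seeded from the data (asymptotes from the
#'   responses at the extreme concentrations, `C` near the half-range
#'   response) and additionally from a plain 4PL fit, then started from
#'   several asymmetry values; the converged solution with the lowest
#'   weighted residual sum of squares is kept.  Shape parameters are kept in
#'   a broad admissible box (`B`, `G` in `[0.2, 5]`, `C` within a factor 8
#'   of the standard range) so the ridge-shaped likelihood of the 5PL cannot
#'   wander into absurd parameter trades.
#' @return A [fivepl_curve()] with attributes `residual_norm` (root sum of
#'   squared residuals) and `n_points`.
#' @export
fit_5pl <- function(standards, lot_id = NA_character_,
                    weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(standards),
            all(c("concentration", "mfi") %in% names(standards)))
  conc <- as.numeric(standards$concentration)
  mfi <- as.numeric(standards$mfi)
  keep <- is.finite(conc) & is.finite(mfi)
  conc <- conc[keep]; mfi <- mfi[keep]
  if (length(unique(conc)) < 6L)
    stop("5PL fit requires at least 6 distinct standard concentrations")
  if (any(mfi <= 0)) stop("standard MFIs must be positive")
  ord <- order(conc)
  conc <- conc[ord]; mfi <- mfi[ord]

  a0 <- mfi[which.min(conc)]
  d0 <- mfi[which.max(conc)]
  if (a0 == d0) d0 <- d0 * 1.01 + 1
  half <- (max(mfi) + min(mfi)) / 2
  c0 <- conc[which.min(abs(mfi - half))]
  if (c0 <= 0) c0 <- stats::median(conc[conc > 0])

  dat <- data.frame(x = conc, y = mfi)
  w <- if (weighting == "relative") 1 / mfi^2 else rep(1, length(mfi))
  lower <- c(A = -Inf, D = -Inf, lC = log(min(conc) / 8), B = 0.2,
             lG = log(0.2))
  upper <- c(A = Inf, D = Inf, lC = log(max(conc) * 8), B = 5, lG = log(5))

  starts <- list(list(A = a0, D = d0, lC = log(c0), B = 1))
  fit4 <- tryCatch(
    minpack.lm::nlsLM(y ~ D + (A - D) / (1 + (x / exp(lC))^B),
                      data = dat, weights = w, start = starts[[1]],
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (!is.null(fit4)) {
    p4 <- stats::coef(fit4)
    starts <- c(starts, list(as.list(p4)))
  }
  best <- NULL
  best_rss <- Inf
  last_err <- NULL
  for (st in starts) for (g0 in c(0, -0.5, 0.5)) {
    st$lG <- g0
    st$lC <- min(max(st$lC, lower[["lC"]]), upper[["lC"]])
    st$B <- min(max(st$B, lower[["B"]]), upper[["B"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ D + (A - D) / (1 + (x / exp(lC))^B)^exp(lG),
        data = dat, weights = w, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) {
      rss <- sum(w * stats::resid(fit)^2)
      if (rss < best_rss) { best_rss <- rss; best <- fit }
    }
  }
  if (is.null(best))
    stop("5PL fit did not converge from any start: ",
         conditionMessage(last_err))
  fit <- best
  p <- stats::coef(fit)
  curve <- fivepl_curve(A = p[["A"]], B = p[["B"]], C = exp(p[["lC"]]),
                        D = p[["D"]], G = exp(p[["lG"]]),
                        valid_range = range(conc), lot_id = lot_id)
  # the 5PL is monotone for any admissible parameters; verify numerically
  # anyway so a pathological fit (e.g. asymptote crossing) is rejected
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 101))
  dy <- diff(eval_5pl(curve, grid))
  if (!(all(dy >= -1e-9 * max(abs(mfi))) || all(dy <= 1e-9 * max(abs(mfi)))))
    stop("fitted 5PL is not monotone over the standard range; fit rejected")
  attr(curve, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(curve, "n_points") <- length(conc)
  curve
}

#' Two-point recalibration of a stored master curve
#'
#' Adjusts a lot-specific master curve to the current run using two adjuster
#' samples of known concentration: an affine transform of the response axis
#' `y' = s y + t` is solved so that the master-curve responses at the two
#' nominal concentrations map onto the measured adjuster MFIs.  Only the
#' asymptotes change (`A' = sA + t`, `D' = sD + t`); the shape parameters
#' `B`, `C`, `G` are retained from the master lot.
#'
#' @param master A [fivepl_curve()].
#' @param adjusters A data frame with two rows and columns `concentration`
#'   (distinct nominal IU/mL) and `mfi` (measured in the current run).
#' @return A recalibrated [fivepl_curve()] with attributes `gain` and
#'   `offset`.
#' @export
recalibrate_two_point <- function(master, adjusters) {
  stopifnot(inherits(master, "fivepl_curve"), is.data.frame(adjusters),
            all(c("concentration", "mfi") %in% names(adjusters)))
  if (nrow(adjusters) != 2L)
    stop("exactly two adjuster points are required")
  if (adjusters$concentration[1] == adjusters$concentration[2])
    stop("adjuster nominal concentrations must be distinct")
  y_master <- eval_5pl(master, adjusters$concentration)
  if (abs(diff(y_master)) < .Machine$double.eps * max(abs(y_master)))
    stop("master curve responses at the adjuster concentrations coincide")
  s <- diff(adjusters$mfi) / diff(y_master)
  if (!is.finite(s) || s <= 0)
    stop("adjusters imply a non-positive response gain (inverted run); ",
         "recalibration refused")
  t <- adjusters$mfi[1] - s * y_master[1]
  out <- fivepl_curve(A = s * master$A + t, B = master$B, C = master$C,
                      D = s * master$D + t, G = master$G,
                      valid_range = master$valid_range, lot_id = master$lot_id)
  attr(out, "gain") <- s
  attr(out, "offset") <- t
  out
}

#' Write / read a master-curve charge certificate
#'
#' Master curves travel between calibration and routine runs as a small JSON
#' "charge certificate": lot identifier, the five parameters, the valid
#' concentration range, the residual norm of the fit and a date stamp.
#'
#' @param curve A [fivepl_curve()].
#' @param path File path for the JSON certificate.
#' @return `write_curve_certificate()` returns `path` invisibly;
#'   `read_curve_certificate()` returns a [fivepl_curve()].
#' @export
write_curve_certificate <- function(curve, path) {
  stopifnot(inherits(curve, "fivepl_curve"))
  obj <- list(lot_id = curve$lot_id,
              parameters = curve[c("A", "B", "C", "D", "G")],
              valid_range = curve$valid_range,
              residual_norm = attr(curve, "residual_norm"),
              fit_date = format(Sys.Date()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_certificate
#' @param path File path of an existing certificate.
#' @export
read_curve_certificate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$parameters
  curve <- fivepl_curve(A = p$A, B = p$B, C = p$C, D = p$D, G = p$G,
                        valid_range = as.numeric(obj$valid_range),
                        lot_id = if (is.null(obj$lot_id)) NA_character_ else obj$lot_id)
  attr(curve, "residual_norm") <- obj$residual_norm
  curve
}
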