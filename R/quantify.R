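#' Standardize a value to percent of the top standard
#'
#' Assay harmonization expresses concentrations (or MFI-derived units) as a
#' percentage of the highest standard-curve point, which is defined as 100%.
#'
#' @param value Numeric value(s) in the same unit as `top_standard`.
#' @param top_standard The highest standard-curve point (> 0).
#' @return `100 * value / top_standard`.
#' @export
standardize_percent <- function(value, top_standard) {
  stopifnot(is.numeric(value), is.numeric(top_standard),
            length(top_standard) == 1L)
  if (!is.finite(top_standard) || top_standard <= 0)
    stop("top_standard must be > 0")
  100 * value / top_standard
}

#' Analyte cut-off table
#'
#' Clinical decision thresholds for the microbead immunoassay, stored on
#' both the IU/mL and the percent-of-top-standard scale.  Defaults are the
#' assay's validated cut-offs: PR3 0.9 IU/mL (8.4%) and MPO 3.0 IU/mL
#' (19.3%).  The per-analyte top standard is derived so that the two scales
#' are mutually consistent under [standardize_percent()].
#'
#' @param cutoff_iu Named numeric, cut-off in IU/mL per analyte.
#' @param cutoff_percent Named numeric, the same cut-offs in percent of the
#'   top standard.
#' @return A data frame with one row per analyte and columns `analyte`,
#'   `cutoff_iu`, `cutoff_percent`, `top_standard_iu`; class `cutoff_table`.
#' @export
cutoff_table <- function(cutoff_iu = c(PR3 = 0.9, MPO = 3.0),
                         cutoff_percent = c(PR3 = 8.4, MPO = 19.3)) {
  analyte <- names(cutoff_iu)
  stopifnot(!is.null(analyte), identical(analyte, names(cutoff_percent)),
            all(cutoff_iu > 0), all(cutoff_percent > 0))
  top <- 100 * cutoff_iu / cutoff_percent
  out <- data.frame(analyte = analyte, cutoff_iu = as.numeric(cutoff_iu),
                    cutoff_percent = as.numeric(cutoff_percent),
                    top_standard_iu = as.numeric(top),
                    stringsAsFactors = FALSE)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Dichotomize a concentration against the analyte cut-off
#'
#' @param conc Concentration(s) in IU/mL, `>= 0`.
#' @param analyte `"PR3"` or `"MPO"` (any analyte present in `cutoffs`).
#' @param cutoffs A [cutoff_table()].
#' @return Character vector `"positive"`/`"negative"`; the cut-off itself is
#'   positive (inclusive boundary).
#' @export
apply_cutoff <- function(conc, analyte, cutoffs = cutoff_table()) {
  stopifnot(is.numeric(conc), inherits(cutoffs, "cutoff_table"))
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  i <- match(analyte, cutoffs$analyte)
  if (anyNA(i))
    stop("unknown analyte: ", paste(analyte[is.na(i)], collapse = ", "))
  ifelse(conc >= cutoffs$cutoff_iu[i], "positive", "negative")
}

#' Intra- and inter-assay coefficient of variation
#'
#' `design = "intra"` computes `100 * sd / mean` over replicate measurements
#' of one run.  `design = "inter"` follows the multi-day scheme (replicates
#' measured on several days): the per-day means are computed first and the
#' CV is taken across those day means.
#'
#' @param replicates Numeric vector of replicate values.  For
#'   `design = "inter"`, either a list of per-day numeric vectors or a data
#'   frame with columns `value` and `day`.
#' @param design `"intra"` or `"inter"`.
#' @return The percent CV (sample standard deviation).
#' @export
assay_cv <- function(replicates, design = c("intra", "inter")) {
  design <- match.arg(design)
  if (design == "inter") {
    if (is.data.frame(replicates)) {
      stopifnot(all(c("value", "day") %in% names(replicates)))
      replicates <- split(replicates$value, replicates$day)
    }
    stopifnot(is.list(replicates))
    replicates <- vapply(replicates, mean, numeric(1))
  }
  replicates <- as.numeric(replicates)
  if (length(replicates) < 2L)
    stop("at least 2 replicates (or days) are required for a CV")
  m <- mean(replicates)
  if (abs(m) < .Machine$double.eps)
    stop("CV undefined: replicate mean is zero")
  100 * stats::sd(replicates) / m
}

#' Functional assay sensitivity (limit of quantification)
#'
#' The lowest detectable concentration whose inter-assay CV is at or below
#' `cv_limit` percent, obtained from a precision profile by interpolating
#' the CV linearly against log concentration between the bracketing profile
#' points.
#'
#' @param precision_profile Data frame with columns `concentration`
#'   (positive, sorted increasing) and `cv` (percent, positive).
#' @param cv_limit CV threshold in percent (default 20).
#' @return The interpolated concentration, the lowest profiled concentration
#'   when the profile never exceeds the limit, or `NA_real_` when the limit
#'   is never reached (with a warning).
#' @export
functional_sensitivity <- function(precision_profile, cv_limit = 20) {
  stopifnot(is.data.frame(precision_profile),
            all(c("concentration", "cv") %in% names(precision_profile)))
  conc <- as.numeric(precision_profile$concentration)
  cv <- as.numeric(precision_profile$cv)
  if (is.unsorted(conc, strictly = TRUE))
    stop("precision profile must be sorted by strictly increasing concentration")
  if (any(conc <= 0) || any(cv <= 0))
    stop("concentrations and CVs must be positive")
  ok <- which(cv <= cv_limit)
  if (length(ok) == 0L) {
    warning("functional sensitivity not reached: all CVs exceed ",
            cv_limit, "%")
    return(NA_real_)
  }
  i <- ok[1]
  if (i == 1L) return(conc[1])
  # log-linear interpolation of the crossing between profile points i-1, i
  lc <- log(conc[c(i - 1L, i)])
  cv2 <- cv[c(i - 1L, i)]
  exp(lc[1] + (cv_limit - cv2[1]) * diff(lc) / diff(cv2))
}

#' Read a calibration-standards table
#'
#' Standards and replicate measurements travel as CSV with columns
#' `analyte`, `concentration`, `mfi` and optionally `run` and `day`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_standards_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "concentration", "mfi")
  if (!all(need %in% names(df)))
    stop("standards CSV must have columns ", paste(need, collapse = ", "))
  df
}
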