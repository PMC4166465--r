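#' ROC analysis with DeLong confidence interval and Youden cut-off
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney)
#' formulation, its confidence interval from the DeLong placement-variance
#' estimator, and the decision threshold maximizing Youden's J
#' (sensitivity + specificity - 1).  A sample is called positive when its
#' score is at or above the threshold; candidate thresholds are the
#' midpoints between consecutive distinct scores plus the two outer
#' extremes.  Ties in J are broken toward the higher-specificity (larger)
#' threshold.
#'
#' @param scores Numeric vector of continuous test values (higher = more
#'   case-like).
#' @param labels Logical, factor or 0/1 vector of the same length; `TRUE`/1
#'   marks cases.
#' @param conf_level Confidence level for the AUC interval.
#' @return A list: `auc`, `conf_int`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `n_cases`, `n_controls`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  lab <- if (is.logical(labels)) labels else
    if (is.factor(labels)) labels == levels(labels)[2] else labels == 1
  keep <- is.finite(scores) & !is.na(lab)
  scores <- scores[keep]; lab <- lab[keep]
  x <- scores[lab]        # cases
  y <- scores[!lab]       # controls
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L)
    stop("ROC analysis requires both cases and controls")

  # rank / Mann-Whitney AUC
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong placements
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(max(var_auc, 0))))

  # Youden-optimal cut-off over midpoint thresholds (positive if >= cutoff)
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) mean(x >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(y < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[length(best)]   # largest threshold = highest specificity
  list(auc = auc, conf_int = ci, cutoff = thr[best],
       sensitivity = sens[best], specificity = spec[best],
       youden = j[best], n_cases = m, n_controls = n)
}
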