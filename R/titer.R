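#' The reciprocal endpoint-titer ladder
#'
#' The doubling ladder of reciprocal serum dilutions used in endpoint-titer
#' reporting.  The lowest rung, 10, is the negative / "<=10" bin: a sample
#' with no positive reaction at any tested dilution is reported there.
#'
#' @return Numeric vector `c(10, 20, 40, 80, 160, 320, 640, 1280, 2560,
#'   5120)`.
#' @export
titer_ladder <- function() {
  c(10, 20, 40, 80, 160, 320, 640, 1280, 2560, 5120)
}

#' @rdname titer_ladder
#' @return `titer_labels()` returns the display labels, `"<=10"` for the
#'   lowest bin.
#' @export
titer_labels <- function() {
  c("<=10", "20", "40", "80", "160", "320", "640", "1280", "2560", "5120")
}

# snap a continuous log2 titer to the nearest ladder rung; exact midpoints
# snap downward (the conservative titer)
snap_to_ladder <- function(log2_titer, ladder = titer_ladder()) {
  steps <- log2(ladder)
  vapply(log2_titer, function(v) {
    d <- abs(steps - v)
    i <- which(d <= min(d) + 1e-12)[1]  # first index = lower rung on ties
    ladder[i]
  }, numeric(1))
}

#' Fit a pattern-dependent single-dilution titer model
#'
#' Learns, separately for the perinuclear (P) and cytoplasmic (C) staining
#' patterns, a monotone mapping from the cell MFI measured at one screening
#' dilution to the classical endpoint titer.  The map is an isotonic
#' (non-decreasing) regression of log2 titer on log MFI, evaluated by linear
#' interpolation between the fitted knots with flat extrapolation beyond the
#' training range.  Separate per-pattern maps absorb the systematic MFI
#' difference between the two patterns at equal titer.
#'
#' @param pairs Data frame with columns `pattern` (`"P"`/`"C"`), `mfi`
#'   (cell MFI at the screening dilution, >= 0) and `titer` (classical
#'   reciprocal endpoint titer on the ladder; the "<=10" bin is coded 10).
#' @param ladder Reciprocal titer ladder (default [titer_ladder()]).
#' @return A `titer_model`: per-pattern knot sets plus a training summary
#'   (`n`, `residual_sd`, MFI range).
#' @export
fit_titer_model <- function(pairs, ladder = titer_ladder()) {
  stopifnot(is.data.frame(pairs),
            all(c("pattern", "mfi", "titer") %in% names(pairs)))
  if (!all(pairs$titer %in% ladder))
    stop("all training titers must lie on the ladder")
  maps <- list()
  for (pat in c("P", "C")) {
    sub <- pairs[pairs$pattern == pat, , drop = FALSE]
    if (nrow(sub) < 5L || length(unique(sub$titer)) < 3L)
      stop("insufficient training span for pattern ", pat,
           ": need >= 5 pairs over >= 3 distinct titers")
    lx <- log(sub$mfi + 1)           # +1 guards the zero-MFI negatives
    ly <- log2(sub$titer)
    iso <- stats::isoreg(lx, ly)
    ox <- iso$x[iso$ord]
    if (is.null(iso$ord)) ox <- iso$x  # isoreg leaves ord NULL when sorted
    knots <- data.frame(x = ox, y = iso$yf)
    # collapse duplicate abscissae (isotonic fit is constant across them)
    knots <- stats::aggregate(y ~ x, knots, mean)
    maps[[pat]] <- list(
      knots = knots,
      mfi_range = range(sub$mfi),
      n = nrow(sub),
      residual_sd = stats::sd(iso$yf - ly[order(lx)]))
  }
  structure(list(maps = maps, ladder = ladder), class = "titer_model")
}

#' @export
print.titer_model <- function(x, ...) {
  cat("Pattern-dependent single-dilution titer model\n")
  for (pat in names(x$maps)) {
    m <- x$maps[[pat]]
    cat(sprintf("  %s: n = %d, MFI range %.3g-%.3g, residual SD %.2f log2 steps\n",
                pat, m$n, m$mfi_range[1], m$mfi_range[2], m$residual_sd))
  }
  invisible(x)
}

#' Predict the endpoint titer from a single-dilution MFI
#'
#' Evaluates the per-pattern monotone map and snaps the continuous log2
#' prediction to the nearest ladder rung (exact midpoints snap downward).
#' A `NEGATIVE` pattern call or an MFI below the model's positivity range
#' (below the smallest training MFI) returns the "<=10" bin by definition.
#'
#' @param model A [fit_titer_model()] result.
#' @param pattern `"P"`, `"C"` or `"NEGATIVE"` (vectorized, recycled
#'   against `mfi`).
#' @param mfi Cell MFI(s) at the screening dilution.
#' @return Reciprocal titer(s) on the ladder (10 = the "<=10" bin).
#' @export
predict_titer <- function(model, pattern, mfi) {
  stopifnot(inherits(model, "titer_model"), is.numeric(mfi))
  nn <- max(length(pattern), length(mfi))
  pattern <- rep_len(pattern, nn)
  mfi <- rep_len(mfi, nn)
  out <- numeric(nn)
  for (i in seq_len(nn)) {
    if (pattern[i] == "NEGATIVE") { out[i] <- model$ladder[1]; next }
    map <- model$maps[[pattern[i]]]
    if (is.null(map)) stop("no titer model fitted for pattern ", pattern[i])
    if (mfi[i] < map$mfi_range[1]) { out[i] <- model$ladder[1]; next }
    l2 <- stats::approx(map$knots$x, map$knots$y, xout = log(mfi[i] + 1),
                        rule = 2, ties = "ordered")$y
    out[i] <- snap_to_ladder(l2, model$ladder)
  }
  out
}

#' Classical endpoint titer from a serial-dilution series
#'
#' The reference procedure: the endpoint titer is the highest reciprocal
#' dilution still giving a positive staining call; an all-negative series is
#' reported as the "<=10" bin.
#'
#' @param series Data frame with columns `dilution` (reciprocal dilutions on
#'   the ladder) and `positive` (logical call at that dilution).
#' @param ladder Reciprocal titer ladder.
#' @return The reciprocal endpoint titer (10 = "<=10").
#' @export
classical_endpoint_titer <- function(series, ladder = titer_ladder()) {
  stopifnot(is.data.frame(series),
            all(c("dilution", "positive") %in% names(series)))
  if (!all(series$dilution %in% ladder))
    stop("dilutions must lie on the titer ladder")
  pos <- series$dilution[as.logical(series$positive)]
  if (length(pos) == 0L) ladder[1] else max(pos)
}

#' Agreement tables for classical vs automated titers
#'
#' Cross-tabulates paired classical and automated endpoint titers on the
#' full 10-rung ladder, collapses the result to the 6 ordered categories
#' `{<=10, 20, 40, 80, 160, >=320}` (all rungs >= 320 merged), and counts
#' how many pairs differ by 0, 1 and more than 1 ladder steps on the full
#' table.
#'
#' @param pairs Data frame with columns `classical` and `automated`
#'   (reciprocal titers on the ladder, 10 = "<=10").
#' @param ladder Reciprocal titer ladder.
#' @return A list: `full` (10x10 [contingency_table()]), `collapsed` (6x6),
#'   and `discordance` (`same`, `one_step`, `more_than_one`, `n`,
#'   `within_one_fraction`).
#' @export
titer_agreement_tables <- function(pairs, ladder = titer_ladder()) {
  stopifnot(is.data.frame(pairs),
            all(c("classical", "automated") %in% names(pairs)))
  if (!all(pairs$classical %in% ladder) || !all(pairs$automated %in% ladder))
    stop("titers must lie on the ladder (code the '<=10' bin as 10)")
  labs <- titer_labels()
  fi <- factor(match(pairs$classical, ladder), levels = seq_along(ladder),
               labels = labs)
  fj <- factor(match(pairs$automated, ladder), levels = seq_along(ladder),
               labels = labs)
  full <- contingency_table(unclass(table(fi, fj)))
  full6 <- collapse_titer_table(full)
  steps <- abs(match(pairs$classical, ladder) - match(pairs$automated, ladder))
  disc <- list(same = sum(steps == 0), one_step = sum(steps == 1),
               more_than_one = sum(steps > 1), n = length(steps),
               within_one_fraction = mean(steps <= 1))
  list(full = full, collapsed = full6, discordance = disc)
}

#' Collapse a full-ladder titer table to six ordered categories
#'
#' Merges all rungs at or above 320 into one `">=320"` category, keeping
#' `{<=10, 20, 40, 80, 160}` as they are.
#'
#' @param full A 10x10 [contingency_table()] on the full ladder.
#' @return A 6x6 [contingency_table()].
#' @export
collapse_titer_table <- function(full) {
  m <- unclass(as.matrix(full))
  if (!all(dim(m) == 10L)) stop("expected a 10x10 full-ladder table")
  g <- c(1:5, rep(6L, 5))
  labs6 <- c("<=10", "20", "40", "80", "160", ">=320")
  out <- matrix(0L, 6, 6, dimnames = list(labs6, labs6))
  for (i in 1:10) for (j in 1:10)
    out[g[i], g[j]] <- out[g[i], g[j]] + m[i, j]
  contingency_table(out)
}
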