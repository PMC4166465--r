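#' Labeled contingency table
#'
#' A thin wrapper around an integer count matrix with row and column labels,
#' the common input to all agreement statistics.
#'
#' @param counts Numeric matrix of non-negative counts (or something
#'   coercible to one).
#' @param row_labels,col_labels Optional dimension labels; taken from
#'   `dimnames(counts)` when present.
#' @return An integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  m <- as.matrix(counts)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be finite non-negative integers")
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  class(m) <- c("contingency_table", class(m))
  m
}

#' Read / write a labeled contingency table as CSV
#'
#' The CSV has the column categories as header and the row categories in the
#' first column.
#'
#' @param path CSV file path.
#' @return `read_table_csv()` returns a [contingency_table()];
#'   `write_table_csv()` returns `path` invisibly.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  contingency_table(m)
}

#' @rdname read_table_csv
#' @param x A [contingency_table()] (or plain matrix).
#' @export
write_table_csv <- function(x, path) {
  df <- data.frame(category = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Shared engine: weighted kappa with agreement weights w (w_ii = 1) and the
# asymptotic (Fleiss-Cohen-Everitt) standard error.  Unweighted kappa is the
# identity-weight special case.
kappa_engine <- function(m, w, conf_level = 0.95) {
  n <- sum(m)
  if (n <= 0) stop("contingency table is empty")
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < .Machine$double.eps)
    stop("kappa undefined: chance agreement is 1 (degenerate margins)")
  k <- (po - pe) / (1 - pe)
  # asymptotic SE of the point estimate (non-null), Fleiss/Cohen/Everitt
  wr <- as.vector(w %*% pc)        # row-associated mean weights
  wc <- as.vector(pr %*% w)        # col-associated mean weights
  term <- outer(wr, wc, function(a, b) (a + b) * (1 - k))
  v <- (sum(p * (w - term)^2) - (k - pe * (1 - k))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = k, se = se,
                 conf_int = c(k - z * se, k + z * se),
                 conf_level = conf_level, n = n, po = po, pe = pe),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%g%% CI %.3f-%.3f), n = %d\n",
              if (is.null(x$weights)) "kappa" else
                paste0("weighted kappa (", x$weights, ")"),
              x$estimate, 100 * x$conf_level,
              x$conf_int[1], x$conf_int[2], x$n))
  invisible(x)
}

#' Cohen's kappa for inter-rater agreement
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement `p_o` the
#' diagonal fraction and chance agreement `p_e` from the table margins.  The
#' confidence interval uses the asymptotic standard error with a normal
#' approximation.
#'
#' @param t A square [contingency_table()] (or count matrix).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `agreement_result` list: `estimate`, `se`, `conf_int`, `n`,
#'   `po`, `pe`.
#' @export
cohens_kappa <- function(t, conf_level = 0.95) {
  m <- unclass(as.matrix(t))
  if (nrow(m) != ncol(m)) stop("kappa requires a square table")
  kappa_engine(m, diag(nrow(m)), conf_level)
}

#' Weighted kappa for ordered categories
#'
#' \eqn{\kappa_w = 1 - \sum v_{ij} n_{ij} / \sum v_{ij} e_{ij}} with
#' disagreement weights \eqn{v_{ij} = |i-j|/(k-1)} (linear) or
#' \eqn{(i-j)^2/(k-1)^2} (quadratic) and expected counts
#' \eqn{e_{ij} = n_{i.} n_{.j} / N}.  Quadratic weights are the default, the
#' conventional choice for ordered titer categories.
#'
#' @param t A square [contingency_table()] with identically ordered row and
#'   column categories.
#' @param weights `"quadratic"` or `"linear"`.
#' @inheritParams cohens_kappa
#' @return An `agreement_result` list (see [cohens_kappa()]), with the
#'   weighting scheme recorded in `$weights`.
#' @export
weighted_kappa <- function(t, weights = c("quadratic", "linear"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  m <- unclass(as.matrix(t))
  k <- nrow(m)
  if (k != ncol(m)) stop("weighted kappa requires a square table")
  d <- abs(row(m) - col(m)) / (k - 1)
  v <- if (weights == "quadratic") d^2 else d
  out <- kappa_engine(m, 1 - v, conf_level)
  out$weights <- weights
  out
}

#' McNemar's test for paired dichotomous ratings
#'
#' Compares two paired classifications via the discordant cells `b` (row
#' positive / column negative) and `c` (row negative / column positive) of a
#' 2x2 table.  Reports the paired difference of proportions
#' `100 (b - c) / N` with a continuity-corrected Wald confidence interval,
#' and by default the exact two-sided binomial p-value of `b` successes in
#' `b + c` trials at p = 1/2 (the asymptotic chi-square test is available
#' with `exact = FALSE`).
#'
#' @param t A 2x2 paired [contingency_table()]; rows and columns ordered
#'   positive, negative.
#' @param exact Use the exact binomial test (default) or the chi-square
#'   approximation with continuity correction.
#' @param conf_level Confidence level for the difference interval.
#' @return A list: `difference_pct`, `conf_int_pct`, `p_value`, `b`, `c`,
#'   `n`, `method`.
#' @export
mcnemar_paired <- function(t, exact = TRUE, conf_level = 0.95) {
  m <- unclass(as.matrix(t))
  if (!all(dim(m) == 2L)) stop("McNemar's test requires a 2x2 table")
  b <- m[1, 2]; cc <- m[2, 1]; n <- sum(m)
  d <- (b - cc) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (b + cc == 0) {
    p <- 1
    ci <- c(0, 0)
  } else {
    if (exact) {
      lo <- min(b, cc); hi <- max(b, cc)
      p <- if (lo == hi) 1 else
        min(1, stats::pbinom(lo, b + cc, 0.5) +
              stats::pbinom(hi - 1L, b + cc, 0.5, lower.tail = FALSE))
    } else {
      p <- stats::mcnemar.test(m, correct = TRUE)$p.value
    }
    se <- sqrt(b + cc - (b - cc)^2 / n) / n
    ci <- d + c(-1, 1) * (z * se + 1 / n)   # continuity-corrected Wald
  }
  list(difference_pct = 100 * d, conf_int_pct = 100 * ci, p_value = p,
       b = as.integer(b), c = as.integer(cc), n = as.integer(n),
       method = if (exact) "exact binomial" else "chi-square")
}
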