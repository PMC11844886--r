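#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution, used to turn the
#' independence-test statistic into a p-value.
#'
#' @param x Non-negative statistic value.
#' @param df Positive integer degrees of freedom.
#' @return Upper-tail probability in (0, 1].
#' @export
chi2_sf <- function(x, df) {
  stopifnot(is.numeric(x), all(x >= 0))
  if (any(df < 1)) stop("df must be a positive integer", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Build an executability contingency table
#'
#' Strategies x {executable, not_executable} counts for one complexity
#' level, the unit of the chi-square test of independence.
#'
#' @param records Trial-record data frame.
#' @param complexity Complexity level to subset on.
#' @return Integer matrix with strategy row names and columns
#'   `executable` / `not_executable`.
#' @export
executability_table <- function(records, complexity) {
  sub <- records[records$complexity == complexity &
                 !isTRUE_vec(records$infra_error) &
                 !is.na(records$executable), , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no trials at complexity ", complexity, call. = FALSE)
  }
  strategies <- unique(sub$strategy)
  counts <- t(vapply(strategies, function(s) {
    e <- sub$executable[sub$strategy == s]
    c(executable = sum(e), not_executable = sum(!e))
  }, c(executable = 0, not_executable = 0)))
  storage.mode(counts) <- "integer"
  counts
}

#' Chi-square test of independence
#'
#' Pearson's chi-square on an r x c contingency table: expected counts are
#' `row_total * col_total / grand_total`, the statistic is
#' `sum((observed - expected)^2 / expected)` with
#' `df = (r - 1) * (c - 1)`, and the p-value is the chi-square upper tail.
#' No continuity correction is applied by default (the benchmark's tables
#' are strategies x 2, df = 4, where none applies); `correct = TRUE`
#' enables the Yates correction for 2 x 2 tables.
#'
#' @param table Non-negative integer matrix, at least 2 x 2.
#' @param correct Apply the Yates continuity correction (2 x 2 only)?
#' @return An object of class `chisq_result` with fields `statistic`,
#'   `df`, `p_value`, `expected`.
#' @export
chisq_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(table)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column total is zero, ",
         "expected counts would be zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (correct && nrow(table) == 2L && ncol(table) == 2L) {
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(list(statistic = statistic, df = df,
                 p_value = chi2_sf(statistic, df), expected = expected),
            class = "chisq_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction over one family of
#' p-values (here: the per-complexity-level tests). Adjusted values are
#' reported in input order, are never smaller than the raw values, and are
#' capped at 1.
#'
#' @param raw_p Non-empty vector of p-values in (0, 1].
#' @return An object of class `adjusted_p` with fields `raw`, `adjusted`,
#'   `method = "BH"`.
#' @export
bh_adjust <- function(raw_p) {
  stopifnot(is.numeric(raw_p))
  if (length(raw_p) == 0L) stop("raw_p must be non-empty", call. = FALSE)
  if (any(raw_p <= 0 | raw_p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(raw = raw_p,
                 adjusted = stats::p.adjust(raw_p, method = "BH"),
                 method = "BH"),
            class = "adjusted_p")
}

#' Significance stars
#'
#' The usual star labels on (adjusted) p-values: `***` below 0.001, `**`
#' below 0.01, `*` below 0.05, `ns` otherwise.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p), all(p > 0 & p <= 1))
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Per-complexity executability tests
#'
#' For every complexity level present in the records: a chi-square test of
#' independence on the strategies x executability table, followed by a
#' Benjamini-Hochberg correction across the levels and star labeling of
#' the adjusted values. Full precision is carried internally; rounding to
#' three significant figures (half away from zero) happens only in
#' [format_executability_tests()].
#'
#' @param records Trial-record data frame covering at least two strategies.
#' @return Data frame with columns `complexity`, `statistic`, `df`,
#'   `p_value`, `adj_p_value`, `significance`.
#' @export
executability_tests <- function(records) {
  levels <- sort(unique(records$complexity))
  tests <- lapply(levels, function(cx) {
    chisq_independence(executability_table(records, cx))
  })
  raw <- vapply(tests, `[[`, 0, "p_value")
  adj <- bh_adjust(raw)$adjusted
  data.frame(
    complexity = levels,
    statistic = vapply(tests, `[[`, 0, "statistic"),
    df = vapply(tests, `[[`, 0L, "df"),
    p_value = raw,
    adj_p_value = adj,
    significance = p_stars(adj),
    stringsAsFactors = FALSE)
}

# Round to k significant figures, halves away from zero (so 3.525e-3 at
# three figures prints 3.53e-3, which plain signif() would round to even).
signif_half_up <- function(x, digits = 3L) {
  out <- x
  nz <- !is.na(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1L
  # small epsilon so binary representation error cannot pull an exact
  # decimal half below the rounding boundary
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5 + 1e-9) * 10^e
  out
}

#' Format / write the executability-test table
#'
#' Display form of [executability_tests()]: statistic and p-values rounded
#' to three significant figures, halves away from zero.
#'
#' @param tests Data frame from [executability_tests()].
#' @return Data frame with formatted columns.
#' @export
format_executability_tests <- function(tests) {
  data.frame(
    complexity = tests$complexity,
    chi_square_statistic = signif_half_up(tests$statistic, 3L),
    p_value = sprintf("%.2e", signif_half_up(tests$p_value, 3L)),
    adj_p_value = sprintf("%.2e", signif_half_up(tests$adj_p_value, 3L)),
    significance = tests$significance,
    stringsAsFactors = FALSE)
}

#' @rdname format_executability_tests
#' @param path Destination CSV file.
#' @export
write_executability_tests <- function(tests, path) {
  utils::write.csv(format_executability_tests(tests), path,
                   row.names = FALSE)
  invisible(path)
}
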