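#' Per-repeat two-condition normalization
#'
#' Within each biological repeat, both condition means are divided by their
#' average: for repeat `i`, `m_i = (A_i + B_i) / 2` and the normalized pair
#' is `(A_i / m_i, B_i / m_i)`. By construction the mean of the two
#' normalized values is exactly 1 in every repeat, which removes
#' between-repeat scale differences while preserving the within-repeat
#' ratio.
#'
#' @param data tibble with one row per (condition, biological repeat) and
#'   positive values; extra rows per cell are averaged first.
#' @param value,condition,repeat_col column names (strings) of the
#'   measurement, the two-level condition and the repeat identifier.
#' @return Tibble with columns `biological_repeat`, `condition`, `raw`
#'   (per-repeat mean), `pair_mean` and `normalized`.
#' @export
#' @examples
#' df <- tibble::tibble(condition = rep(c("a", "b"), 3),
#'                      biological_repeat = rep(1:3, each = 2),
#'                      y = c(2, 1, 4, 2, 3, 3))
#' two_condition_normalize(df, "y")
two_condition_normalize <- function(data, value, condition = "condition",
                                    repeat_col = "biological_repeat") {
  stopifnot(all(c(value, condition, repeat_col) %in% names(data)))
  df <- tibble::tibble(condition = data[[condition]],
                       biological_repeat = data[[repeat_col]],
                       raw = data[[value]])
  conds <- unique(df$condition)
  if (length(conds) != 2) {
    stop("two_condition_normalize requires exactly 2 conditions, got ",
         length(conds))
  }
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$biological_repeat, .data$condition),
    raw = mean(.data$raw), .groups = "drop")
  counts <- table(df$biological_repeat)
  if (any(counts != 2)) {
    stop("every biological repeat must have both conditions")
  }
  if (any(!is.finite(df$raw)) || any(df$raw <= 0)) {
    stop("values must be positive and finite for the normalization rule")
  }
  # the complement form keeps the per-repeat normalized mean at exactly 1
  # in floating point, not just in exact arithmetic
  df <- dplyr::mutate(dplyr::group_by(df, .data$biological_repeat),
                      pair_mean = mean(.data$raw),
                      normalized = {
                        v <- .data$raw / .data$pair_mean
                        v[2] <- 2 - v[1]
                        v
                      })
  dplyr::ungroup(df)
}

stars_for_p <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare two conditions across biological repeats
#'
#' The statistics layer used for every readout: per-repeat condition means
#' are normalized to the average of both conditions within each repeat
#' (see [two_condition_normalize()]; disable with `normalize = FALSE`) and
#' compared with a two-tailed paired or unpaired t test. The unpaired test
#' uses the pooled-variance Student form by default (`welch = TRUE` for the
#' Welch form). Raw p-values are reported (no multiple-testing correction)
#' with significance stars mapped as *p<0.05, **p<0.01, ***p<0.001,
#' ****p<0.0001. Zero-variance differences make the test degenerate: the
#' statistic and p-value are `NA` and `degenerate` is set.
#'
#' @param data tibble with condition, repeat and value columns (one or more
#'   rows per condition x repeat; rows are averaged per repeat first).
#' @param value,condition,repeat_col column names (strings).
#' @param test `"paired_t"` or `"unpaired_t"`.
#' @param normalize apply the per-repeat two-condition normalization before
#'   testing (default `TRUE`).
#' @param welch use the Welch unpaired form.
#' @param measure_name label carried into the result.
#' @return Object of class `repeat_comparison`; see [tidy.repeat_comparison()]
#'   and [glance.repeat_comparison()].
#' @export
#' @examples
#' df <- tibble::tibble(condition = rep(c("mock", "aza"), 3),
#'                      biological_repeat = rep(1:3, each = 2),
#'                      y = c(1.0, 0.52, 1.1, 0.55, 0.95, 0.49))
#' compare_conditions(df, "y", test = "paired_t")
compare_conditions <- function(data, value, condition = "condition",
                               repeat_col = "biological_repeat",
                               test = c("paired_t", "unpaired_t"),
                               normalize = TRUE, welch = FALSE,
                               measure_name = value) {
  test <- match.arg(test)
  norm <- two_condition_normalize(data, value, condition, repeat_col)
  conds <- unique(norm$condition)
  use_col <- if (normalize) "normalized" else "raw"
  a <- norm[[use_col]][norm$condition == conds[1]][
    order(norm$biological_repeat[norm$condition == conds[1]])]
  b <- norm[[use_col]][norm$condition == conds[2]][
    order(norm$biological_repeat[norm$condition == conds[2]])]
  n <- length(a)
  if (n < 2) stop("need at least 2 biological repeats")
  degenerate <- FALSE
  if (test == "paired_t") {
    d <- a - b
    if (stats::sd(d) == 0) {
      degenerate <- TRUE
      statistic <- if (all(d == 0)) 0 else NA_real_
      p <- if (all(d == 0)) 1 else NA_real_
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0 && mean(a) == mean(b)) {
      degenerate <- TRUE; statistic <- 0; p <- 1
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degenerate <- TRUE; statistic <- NA_real_; p <- NA_real_
    } else {
      ht <- stats::t.test(a, b, paired = FALSE, var.equal = !welch)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  structure(list(measure_name = measure_name, conditions = conds,
                 per_repeat = norm, test = test, welch = welch,
                 normalized = normalize, statistic = statistic,
                 p_value = p, stars = stars_for_p(p),
                 n_repeats = n, degenerate = degenerate),
            class = "repeat_comparison")
}

#' @export
print.repeat_comparison <- function(x, ...) {
  cat(sprintf("<repeat_comparison> %s: %s vs %s (n = %d repeats)\n",
              x$measure_name, x$conditions[1], x$conditions[2], x$n_repeats))
  lbl <- if (x$test == "paired_t") "paired t" else
    if (x$welch) "Welch unpaired t" else "unpaired t (pooled variance)"
  cat(sprintf("  %s: t = %.4g, two-tailed p = %.4g %s%s\n", lbl,
              x$statistic, x$p_value, x$stars,
              if (x$degenerate) " [degenerate]" else ""))
  means <- tapply(x$per_repeat$normalized, x$per_repeat$condition, mean)
  cat(sprintf("  normalized means: %s = %.3f, %s = %.3f\n",
              names(means)[1], means[1], names(means)[2], means[2]))
  invisible(x)
}

#' One-way analysis of variance across groups
#'
#' Classical between/within-group F with its p-value, used when more than
#' two conditions are compared. A group with zero variance is allowed;
#' when all groups are constant and identical the result is the degenerate
#' `F = 0, p = 1`.
#'
#' @param data tibble with a value and a grouping column.
#' @param value,group column names (strings).
#' @return Object of class `repeat_anova`: list with `statistic` (F),
#'   `p_value`, `df_between`, `df_within`, `n_groups`, `degenerate`.
#' @export
one_way_anova <- function(data, value, group = "condition") {
  stopifnot(all(c(value, group) %in% names(data)))
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) stop("one_way_anova needs at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  if (stats::sd(y) == 0) {
    res <- list(statistic = 0, p_value = 1, degenerate = TRUE)
  } else {
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    res <- list(statistic = unname(ft$statistic),
                p_value = ft$p.value, degenerate = FALSE)
  }
  structure(c(res, list(df_between = df_b, df_within = df_w,
                        n_groups = nlevels(g),
                        stars = stars_for_p(res$p_value))),
            class = "repeat_anova")
}

#' @export
print.repeat_anova <- function(x, ...) {
  cat(sprintf("<repeat_anova> F(%d, %d) = %.4g, p = %.4g %s%s\n",
              x$df_between, x$df_within, x$statistic, x$p_value, x$stars,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
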