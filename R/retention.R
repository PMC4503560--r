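# Retention scores and the significance procedure.
#
# The retention score (RS) of an IES is IES+ / (IES+ + IES-): 0 means
# complete excision, 1 complete retention. An IES is called significantly
# retained in the experiment when a one-sided binomial test of the
# experimental IES+ count against the UPPER bound of the exact
# (Clopper-Pearson) confidence interval of the control RS yields a
# Benjamini-Hochberg adjusted p-value below the threshold. Testing the
# interval bound rather than the control point estimate makes the call
# conservative for well-covered controls.

#' Retention score
#'
#' `n_plus / (n_plus + n_minus)`; `NA` when the denominator is zero.
#'
#' @param n_plus,n_minus Non-negative integer counts (vectorized).
#' @return Numeric vector in `[0, 1]` with `NA` for uncovered IESs.
#' @export
#' @examples
#' retention_score(0, 50)   # complete excision
#' retention_score(10, 30)  # 0.25
retention_score <- function(n_plus, n_minus) {
  assert_counts(n_plus, "n_plus")
  assert_counts(n_minus, "n_minus")
  total <- n_plus + n_minus
  ifelse(total == 0, NA_real_, n_plus / total)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion at confidence level
#' `alpha`, computed by inversion of the binomial CDF (beta quantile
#' form). `low = 0` when `x = 0` and `high = 1` when `x = n`.
#'
#' @param x Successes, `0 <= x <= n` (vectorized).
#' @param n Trials, `n >= 1`.
#' @param alpha Confidence level in `(0, 1)` (default 0.95).
#' @return A tibble with columns `low`, `high`.
#' @export
#' @examples
#' clopper_pearson(0, 10)  # high = 1 - 0.025^(1/10)
clopper_pearson <- function(x, n, alpha = 0.95) {
  assert_counts(x, "x")
  assert_counts(n, "n")
  if (any(n < 1) || any(x > n)) abort("need 0 <= x <= n and n >= 1")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1)")
  tail <- (1 - alpha) / 2
  low <- ifelse(x == 0, 0, qbeta(tail, x, n - x + 1))
  high <- ifelse(x == n, 1, qbeta(1 - tail, x + 1, n - x))
  tibble(low = low, high = high)
}

#' One-sided upper-tail binomial p-value
#'
#' `P(X >= x)` for `X ~ Binomial(n, p0)`; equals 1 when `x = 0` or
#' `p0 = 1`.
#'
#' @param x Observed count (vectorized).
#' @param n Trials.
#' @param p0 Null proportion in `[0, 1]`.
#' @return Numeric p-values in `(0, 1]`.
#' @export
binomial_tail_pvalue <- function(x, n, p0) {
  assert_counts(x, "x")
  assert_counts(n, "n")
  if (any(x > n)) abort("need x <= n")
  if (any(p0 < 0 | p0 > 1)) abort("`p0` must lie in [0, 1]")
  pmin(1, pbinom(x - 1, n, p0, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, input order preserved).
#'
#' @param pvalues Numeric vector in `(0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call significantly retained IESs against a control sample
#'
#' Per IES: the control RS and its exact Clopper-Pearson interval at
#' confidence `alpha`; a one-sided binomial test of the experimental IES+
#' count (`n` = experimental coverage, null proportion = upper bound of
#' the control interval); BH adjustment across all tested IESs; a
#' `retained` call when the adjusted p-value is strictly below
#' `threshold`. IESs with coverage below `min_coverage` in either sample
#' are excluded from testing and reported with `NA` statistics (they never
#' enter the BH family).
#'
#' @param exp_counts,ctrl_counts Counts tibbles (`ies_id`, `n_plus`,
#'   `n_minus`) over the same IES catalog.
#' @param alpha Confidence level of the control interval (default 0.95).
#' @param threshold Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param min_coverage Minimum `n_plus + n_minus` required in each sample
#'   for an IES to be tested (default 1).
#' @return An object of class `ies_retention_call`; see [tidy()] /
#'   [glance()] methods, `$results` holds the per-IES tibble.
#' @export
call_retention <- function(exp_counts, ctrl_counts, alpha = 0.95,
                           threshold = 0.05, min_coverage = 1L) {
  exp_counts <- as_tibble(exp_counts)
  ctrl_counts <- as_tibble(ctrl_counts)
  if (!setequal(exp_counts$ies_id, ctrl_counts$ies_id) ||
      nrow(exp_counts) != nrow(ctrl_counts)) {
    abort("experiment and control counts must cover the same IES catalog")
  }
  assert_scalar_number(min_coverage, "min_coverage", lower = 1)
  df <- left_join(
    rename(ctrl_counts, n_plus_control = "n_plus", n_minus_control = "n_minus"),
    rename(exp_counts, n_plus_experiment = "n_plus",
           n_minus_experiment = "n_minus"),
    by = "ies_id"
  )
  df <- mutate(
    df,
    n_control = .data$n_plus_control + .data$n_minus_control,
    n_experiment = .data$n_plus_experiment + .data$n_minus_experiment,
    rs_control = retention_score(.data$n_plus_control, .data$n_minus_control),
    rs_experiment = retention_score(.data$n_plus_experiment,
                                    .data$n_minus_experiment),
    tested = .data$n_control >= min_coverage & .data$n_experiment >= min_coverage
  )
  ci_low <- rep(NA_real_, nrow(df))
  ci_high <- rep(NA_real_, nrow(df))
  pvalue <- rep(NA_real_, nrow(df))
  padj <- rep(NA_real_, nrow(df))
  t <- df$tested
  if (any(t)) {
    ci <- clopper_pearson(df$n_plus_control[t], df$n_control[t], alpha)
    ci_low[t] <- ci$low
    ci_high[t] <- ci$high
    pvalue[t] <- binomial_tail_pvalue(df$n_plus_experiment[t],
                                      df$n_experiment[t], ci$high)
    padj[t] <- bh_adjust(pvalue[t])
  }
  results <- df |>
    mutate(ci_low = ci_low, ci_high = ci_high, pvalue = pvalue, padj = padj,
           retained = if_else(.data$tested, .data$padj < threshold, NA)) |>
    select("ies_id", "n_plus_control", "n_minus_control", "rs_control",
           "ci_low", "ci_high", "n_plus_experiment", "n_minus_experiment",
           "rs_experiment", "pvalue", "padj", "tested", "retained")
  structure(
    list(results = results, alpha = alpha, threshold = threshold,
         min_coverage = as.integer(min_coverage)),
    class = "ies_retention_call"
  )
}

#' @export
print.ies_retention_call <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("IES retention call: %d IESs, %d tested, %d retained ",
                     "(%.1f%% of tested) at BH-adjusted p < %g\n"),
              g$n_ies, g$n_tested, g$n_retained,
              100 * g$retained_fraction, x$threshold))
  invisible(x)
}

#' Tidy a retention call
#'
#' @param x An `ies_retention_call`.
#' @param ... Unused.
#' @return The per-IES results tibble.
#' @export
tidy.ies_retention_call <- function(x, ...) {
  x$results
}

#' One-row summary of a retention call
#'
#' @param x An `ies_retention_call`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of IESs, tested and retained IESs,
#'   retained fraction among tested, mean retention scores, and the
#'   calling parameters.
#' @export
glance.ies_retention_call <- function(x, ...) {
  r <- x$results
  n_tested <- sum(r$tested)
  n_retained <- sum(r$retained, na.rm = TRUE)
  tibble(
    n_ies = nrow(r),
    n_tested = n_tested,
    n_retained = n_retained,
    retained_fraction = if (n_tested > 0) n_retained / n_tested else NA_real_,
    mean_rs_control = mean(r$rs_control, na.rm = TRUE),
    mean_rs_experiment = mean(r$rs_experiment, na.rm = TRUE),
    alpha = x$alpha,
    threshold = x$threshold,
    min_coverage = x$min_coverage
  )
}

#' Write retention results
#'
#' Tab-separated per-IES table (scores and p-values at 6 decimal places
#' for stable diffs), followed by a one-line summary comment.
#'
#' @param x An `ies_retention_call`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_retention_results <- function(x, path) {
  stopifnot(inherits(x, "ies_retention_call"))
  r <- x$results
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  out <- tibble(
    ies_id = r$ies_id,
    rs_ctrl = fmt(r$rs_control),
    ci_low = fmt(r$ci_low), ci_high = fmt(r$ci_high),
    rs_exp = fmt(r$rs_experiment),
    pvalue = fmt(r$pvalue), padj = fmt(r$padj),
    retained = ifelse(is.na(r$retained), "NA", ifelse(r$retained, "TRUE", "FALSE"))
  )
  g <- glance(x)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# tested=%d retained=%d retained_fraction=%.6f",
                     g$n_tested, g$n_retained, g$retained_fraction), con)
  invisible(path)
}
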