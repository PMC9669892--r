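#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained from beta
#' quantiles (equivalently, quantiles of the F distribution). The lower
#' bound is 0 when `k = 0` and the upper bound is 1 when `k = n`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param alpha two-sided error level; the default 0.05 gives a 95%
#'   interval.
#' @return named numeric vector `c(low, high)` of proportions.
#' @examples
#' clopper_pearson(423, 953) # 0.412 to 0.476
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) || n < 1) {
    abort("clopper_pearson() needs scalar k and n with n >= 1")
  }
  if (k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' A data-quality indicator result
#'
#' One rate -- completeness or concordance -- with its numerator,
#' denominator, and exact 95% confidence interval, tagged with the
#' observation level it was computed at (family, profile, or episode).
#'
#' @param indicator `"completeness"` or `"concordance"`.
#' @param variable name of the data element the rate refers to.
#' @param k numerator (agreements / submitted elements).
#' @param n denominator (possible matches / source total), `n >= 1`.
#' @param level `"family"`, `"profile"`, or `"episode"`.
#' @param alpha error level for the Clopper-Pearson interval.
#' @return a one-row tibble of class `dqi_result` with columns `indicator`,
#'   `variable`, `level`, `k`, `n`, `rate`, `ci_low`, `ci_high`.
#' @export
dqi_result <- function(indicator = c("completeness", "concordance"),
                       variable, k, n,
                       level = c("episode", "profile", "family"),
                       alpha = 0.05) {
  indicator <- match.arg(indicator)
  level <- match.arg(level)
  ci <- clopper_pearson(k, n, alpha)
  out <- tibble::tibble(
    indicator = indicator, variable = variable, level = level,
    k = as.integer(k), n = as.integer(n), rate = k / n,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]))
  class(out) <- c("dqi_result", class(out))
  out
}

#' @rdname dqi_result
#' @param agreements number of value matches between the sources.
#' @param comparable number of possible matches (episodes present in both
#'   sources).
#' @export
concordance_rate <- function(agreements, comparable, variable = "overall",
                             level = "episode", alpha = 0.05) {
  dqi_result("concordance", variable, agreements, comparable, level, alpha)
}

#' @rdname dqi_result
#' @param source_total episode total of the source used as the
#'   completeness denominator.
#' @export
completeness_rate <- function(agreements, source_total, variable = "overall",
                              level = "episode", alpha = 0.05) {
  dqi_result("completeness", variable, agreements, source_total, level, alpha)
}

#' Chi-square test for a 2x2 table with Yates continuity correction
#'
#' The statistic is `N * (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)` with the
#' continuity term capped at zero, so a perfectly proportional table
#' yields 0. The cap makes the marginal form identical to the cell-sum
#' form `sum((|O - E| - min(0.5, |O - E|))^2 / E)`.
#'
#' @param table 2x2 matrix of counts, or the count `a` with `b`, `c`, `d`
#'   supplied separately (rows = groups, columns = agree/disagree).
#' @param b,c,d remaining cells when `table` is given as a scalar `a`.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list with `statistic`, `df` (1), `p_value`, `corrected`.
#' @examples
#' chi_square_yates(90, 334, 20, 242)$statistic # 21.225
#' @export
chi_square_yates <- function(table, b = NULL, c = NULL, d = NULL,
                             correct = TRUE) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  cells <- as.numeric(base::c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("all four cell counts must be non-negative")
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- sum(cells)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(base::c(r1, r2, c1, c2) == 0)) {
    abort("chi-square is undefined when a marginal total is zero")
  }
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       corrected = correct)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Rank-sum comparison of two samples with midrank handling of ties:
#' exact enumeration for small tie-free samples, otherwise the normal
#' approximation with tie correction (delegated to
#' [stats::wilcox.test()]). Used here to compare temperature differences
#' between acute and past fever episodes.
#'
#' @param x,y non-empty numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   `NULL` chooses exact for tie-free samples with `n <= 20` per group.
#' @return list with `statistic` (the rank-sum statistic W for `x`) and
#'   `p_value` (two-sided).
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty")
  }
  if (is.null(exact)) exact <- length(x) <= 20 && length(y) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Check an indicator against its quality threshold
#'
#' Registries conventionally require completeness and concordance rates of
#' at least 95%; the threshold is not scientifically validated and is a
#' plain parameter here. The comparison is inclusive: a rate exactly at
#' the threshold passes.
#'
#' @param dqi a [dqi_result()] row (or any list with a `rate` element).
#' @param threshold required minimum rate.
#' @return `TRUE` when `rate >= threshold`.
#' @export
threshold_check <- function(dqi, threshold = 0.95) {
  rate <- if (is.data.frame(dqi)) dqi$rate else dqi[["rate"]]
  rate >= threshold
}

#' Median, quartiles, and range
#'
#' Quartiles use the inclusive linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param values non-empty numeric vector; `NA` values are dropped.
#' @return named numeric vector `median`, `q1`, `q3`, `min`, `max`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("median_iqr() needs at least one value")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3],
    min = min(values), max = max(values))
}

#' Format p-values in report style
#'
#' Values below 0.001 print as `"<.001"`.
#' @param p numeric p-value.
#' @return character scalar.
#' @export
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<.001" else sub("^0", "", sprintf("%.3f", p))
}
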