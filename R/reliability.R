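#' Paired test-retest outcomes
#'
#' @param subject subject identifiers.
#' @param test,retest session-1 and session-2 values (same length >= 2,
#'   finite).
#' @param outcome outcome name (e.g. `"whole_striatum ki"`).
#' @return A `paired_outcomes` data frame.
#' @export
paired_outcomes <- function(subject, test, retest, outcome = "outcome") {
  if (length(test) != length(retest) || length(subject) != length(test))
    stop("subject, test and retest must have equal lengths", call. = FALSE)
  if (length(test) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!all(is.finite(test)) || !all(is.finite(retest)))
    stop("values must be finite", call. = FALSE)
  out <- data.frame(subject = subject, test = as.numeric(test),
                    retest = as.numeric(retest))
  attr(out, "outcome") <- outcome
  class(out) <- c("paired_outcomes", "data.frame")
  out
}

#' Two-way mixed-model intraclass correlation
#'
#' Single-measure ICC from the subject-by-session ANOVA decomposition.
#' The default `"consistency"` form is ICC(3,1) =
#' `(BMS - EMS) / (BMS + (k-1) EMS)`, invariant to per-session additive
#' shifts; `"agreement"` is ICC(2,1), which additionally penalizes a session
#' (rater) effect.
#'
#' @param data a [paired_outcomes()] (n >= 3 subjects).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level if non-`NULL`, an F-distribution confidence interval is
#'   attached (consistency form).
#' @return The ICC (numeric scalar, attribute `type`; optional attribute
#'   `conf_int`).
#' @export
icc_two_way <- function(data, type = c("consistency", "agreement"),
                        conf_level = NULL) {
  stopifnot(inherits(data, "paired_outcomes"))
  type <- match.arg(type)
  n <- nrow(data)
  if (n < 3L) stop("ICC requires at least 3 subjects", call. = FALSE)
  k <- 2L
  m <- cbind(data$test, data$retest)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  subj_means <- rowMeans(m)
  sess_means <- colMeans(m)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_sess <- n * sum((sess_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  bms <- ss_subj / (n - 1)
  cms <- ss_sess / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  icc <- switch(type,
    consistency = (bms - ems) / (bms + (k - 1) * ems),
    agreement = (bms - ems) / (bms + (k - 1) * ems + k * (cms - ems) / n))
  attr(icc, "type") <- type
  if (!is.null(conf_level)) {
    if (ems > 0) {
      alpha <- 1 - conf_level
      fobs <- bms / ems
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      attr(icc, "conf_int") <- c((fl - 1) / (fl + k - 1),
                                 (fu - 1) / (fu + k - 1))
    } else attr(icc, "conf_int") <- c(1, 1)
  }
  icc
}

#' Within-subject percent test-retest variability
#'
#' Mean over subjects of `100 * |test - retest| / mean(test, retest)`.
#' Pairs with a zero denominator are excluded with a warning.
#'
#' @param data a [paired_outcomes()].
#' @param denominator `"pair_mean"` (default) normalizes by the within-pair
#'   mean; `"session1"` normalizes by the first session's value.
#' @return `var_pct` (numeric scalar, >= 0).
#' @export
percent_var <- function(data, denominator = c("pair_mean", "session1")) {
  stopifnot(inherits(data, "paired_outcomes"))
  denominator <- match.arg(denominator)
  pm <- switch(denominator,
               pair_mean = (data$test + data$retest) / 2,
               session1 = data$test)
  ok <- pm != 0
  if (!all(ok)) {
    warning(sprintf("%d pair(s) with zero mean excluded from %%VAR",
                    sum(!ok)))
    if (!any(ok)) stop("all pairs have zero mean", call. = FALSE)
  }
  mean(100 * abs(data$test - data$retest)[ok] / pm[ok])
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of test - retest differences) and 95% limits of agreement
#' `bias +/- 1.96 * sd(differences)`; per-pair averages and differences are
#' returned for plotting.
#'
#' @param data a [paired_outcomes()].
#' @return A list: `bias`, `loa_low`, `loa_high`, `sd_diff`, and `pairs`
#'   (data frame with `average`, `difference`).
#' @export
bland_altman <- function(data) {
  stopifnot(inherits(data, "paired_outcomes"))
  d <- data$test - data$retest
  bias <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else 0
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s,
       pairs = data.frame(average = (data$test + data$retest) / 2,
                          difference = d))
}

#' Between-method agreement: Pearson r and mean absolute percent difference
#'
#' @param a,b numeric vectors of matched measurements (n >= 3).
#' @return A list: `pearson_r`, `mapd_pct` (mean of
#'   `100 * |a - b| / ((a + b) / 2)`).
#' @export
agreement_summary <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  list(pearson_r = stats::cor(a, b),
       mapd_pct = mean(100 * abs(a - b) / ((a + b) / 2)))
}

#' Full reliability summary for a paired outcome
#'
#' Bundles [icc_two_way()], [percent_var()], [bland_altman()] and
#' [agreement_summary()] into a single `reliability_result`.
#'
#' @param data a [paired_outcomes()].
#' @param icc_type passed to [icc_two_way()].
#' @return A `reliability_result`: `icc`, `var_pct`, `bias`, `loa_low`,
#'   `loa_high`, `pearson_r`, `mapd_pct`, `outcome`, `n`.
#' @export
reliability_summary <- function(data, icc_type = "consistency") {
  stopifnot(inherits(data, "paired_outcomes"))
  ba <- bland_altman(data)
  ag <- agreement_summary(data$test, data$retest)
  structure(list(icc = as.numeric(icc_two_way(data, type = icc_type)),
                 icc_type = icc_type,
                 var_pct = percent_var(data),
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 pearson_r = ag$pearson_r, mapd_pct = ag$mapd_pct,
                 outcome = attr(data, "outcome"), n = nrow(data)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Reliability [%s], n = %d:\n", x$outcome, x$n))
  cat(sprintf("  ICC (%s)  %.3f\n", x$icc_type, x$icc))
  cat(sprintf("  %%VAR      %.2f\n", x$var_pct))
  cat(sprintf("  bias      %.5g  [LoA %.5g, %.5g]\n", x$bias, x$loa_low,
              x$loa_high))
  cat(sprintf("  Pearson r %.3f, MAPD %.2f%%\n", x$pearson_r, x$mapd_pct))
  invisible(x)
}
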