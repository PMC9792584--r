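#' Per-axis root-mean-square error
#'
#' @param estimates,references Matrices (n x 2) or lists of 2-vectors, in
#'   millimeters, columns/components ordered (AP, ML).
#' @return List with `rmse_ap`, `rmse_ml` (mm) and `n`.
#' @export
rmse_per_axis <- function(estimates, references) {
  est <- as_two_col(estimates)
  ref <- as_two_col(references)
  if (nrow(est) != nrow(ref)) stop("estimate/reference length mismatch")
  if (nrow(est) < 1L) stop("need at least one pair")
  d <- est - ref
  list(rmse_ap = sqrt(mean(d[, 1]^2)), rmse_ml = sqrt(mean(d[, 2]^2)),
       n = nrow(est))
}

as_two_col <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected two columns (AP, ML)")
  x
}

#' Group summary statistics (mean, SD, CV, range)
#'
#' Sample standard deviation (n - 1 denominator) and coefficient of
#' variation in percent, as reported for per-subject RMSE columns.
#'
#' @param values Numeric vector (e.g. per-subject RMSEs in mm), `n >= 2`.
#' @return List with `mean`, `sd`, `cv` (percent), `min`, `max`, `n`.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 for a sample SD")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s,
       cv = if (m != 0) 100 * s / m else NA_real_,
       min = min(values), max = max(values), n = length(values))
}

#' Correlation between estimates and reference readings
#'
#' @param estimates,references Numeric vectors (mm), equal length `>= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` (coefficient), `p_value`, `method`, `n`.
#' @export
correlation <- function(estimates, references,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(estimates) != length(references)) stop("length mismatch")
  if (length(estimates) < 3L) stop("need n >= 3")
  if (stats::sd(estimates) == 0 || stats::sd(references) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(estimates, references, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(estimates))
}

#' Bland-Altman agreement: fixed bias and limits of agreement
#'
#' Differences are taken as estimate minus reference. The fixed bias is
#' their mean; the 95% limits of agreement are `bias +/- 1.96 * SD`; the
#' 95% CI of the bias uses the normal approximation
#' `bias +/- 1.96 * SD / sqrt(n)` by default, or a t-quantile when
#' `ci = "t"`.
#'
#' @param estimates,references Numeric vectors (mm), equal length `>= 3`.
#' @param ci `"normal"` (default) or `"t"`.
#' @return List with `fixed_bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `bias_ci` (length-2), `n` (all mm).
#' @export
bland_altman <- function(estimates, references, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  if (length(estimates) != length(references)) stop("length mismatch")
  n <- length(estimates)
  if (n < 3L) stop("need n >= 3")
  d <- estimates - references
  bias <- mean(d)
  s <- stats::sd(d)
  q <- if (ci == "normal") 1.96 else stats::qt(0.975, n - 1)
  list(fixed_bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       bias_ci = c(bias - q * s / sqrt(n), bias + q * s / sqrt(n)),
       n = n)
}

#' Proportional-bias regression on a Bland-Altman plot
#'
#' Regresses the difference (estimate - reference) on the pairwise mean of
#' estimate and reference. A non-zero slope indicates proportional bias.
#' Because repeated postures from one subject are not independent, the
#' default standard errors are cluster-robust by subject; plain OLS and a
#' per-subject-mean regression are available.
#'
#' @param estimates,references Numeric vectors (mm), equal length `>= 3`.
#' @param subject_id Per-sample subject labels (required for
#'   `mode = "cluster"`).
#' @param mode `"cluster"` (default), `"ols"`, or `"subject_mean"`.
#' @return List with `slope`, `intercept` (mm), `r_squared`, `p_slope`,
#'   `mode`, `n`.
#' @export
proportional_bias_regression <- function(estimates, references,
                                         subject_id = NULL,
                                         mode = c("cluster", "ols",
                                                  "subject_mean")) {
  mode <- match.arg(mode)
  if (length(estimates) != length(references)) stop("length mismatch")
  if (length(estimates) < 3L) stop("need n >= 3")
  diff <- estimates - references
  avg <- (estimates + references) / 2
  if (stats::sd(avg) == 0) stop("slope undefined: constant mean values")
  if (mode == "subject_mean") {
    if (is.null(subject_id)) stop("subject_id required for subject_mean mode")
    diff <- tapply(diff, subject_id, mean)
    avg <- tapply(avg, subject_id, mean)
  }
  fit <- stats::lm(diff ~ avg)
  r2 <- summary(fit)$r.squared
  if (mode == "cluster") {
    if (is.null(subject_id)) stop("subject_id required for cluster mode")
    vc <- sandwich::vcovCL(fit, cluster = subject_id)
    ct <- lmtest::coeftest(fit, vcov. = vc)
    p <- ct["avg", "Pr(>|t|)"]
  } else {
    p <- summary(fit)$coefficients["avg", "Pr(>|t|)"]
  }
  list(slope = unname(stats::coef(fit)["avg"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = r2, p_slope = unname(p), mode = mode,
       n = length(estimates))
}

#' Normality-gated two-group comparison
#'
#' Mirrors the standard comparison protocol: Shapiro-Wilk on each group (on
#' the paired differences when `paired = TRUE`); if normality is not
#' rejected at `alpha`, a Student's t-test (paired t-test) is used,
#' otherwise a Mann-Whitney U test (Wilcoxon signed-rank test).
#'
#' @param a,b Numeric vectors, `n >= 3` each; equal lengths when paired.
#' @param paired Logical.
#' @param alpha Significance level for both the gate and the test.
#' @return List with `test` (name), `parametric` (logical), `statistic`,
#'   `p_value`, `significant`, `shapiro_p` (per input), `degenerate`
#'   (logical: zero-variance input, no test performed).
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("need n >= 3 per group")
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal lengths")
  }
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    return(list(test = "none (degenerate: zero variance)", parametric = NA,
                statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, shapiro_p = c(NA_real_, NA_real_),
                degenerate = TRUE))
  }
  sw <- if (paired) {
    p <- stats::shapiro.test(a - b)$p.value
    c(p, p)
  } else {
    c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
  }
  parametric <- all(sw > alpha)
  if (parametric) {
    ht <- stats::t.test(a, b, paired = paired)
    test <- if (paired) "paired t-test" else "Student's t-test"
  } else {
    ht <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  list(test = test, parametric = parametric,
       statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, shapiro_p = sw, degenerate = FALSE)
}

#' Bundled per-subject RMSE transcription
#'
#' Loads the packaged CSV of per-subject CoM RMSE values (mm) for the two
#' cohorts (fit, obese) and two estimators (SESC, segmental) along the AP
#' and ML axes, as printed in the source study's per-subject result tables.
#'
#' @return Data frame with columns `group`, `subject`, `sesc_ap`, `sesc_ml`,
#'   `segmental_ap`, `segmental_ml`.
#' @export
load_rmse_table <- function() {
  path <- system.file("extdata", "tables_1_2_rmse.csv", package = "sescom",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
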