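# Method-agreement statistics for paired angle measurements and Graf type
# classifications: mean difference and its sample SD, mean absolute error,
# Bland-Altman limits of agreement (mean +/- 1.96 SD), ICC(2,1) with an
# F-based 95% CI, classification agreement rate, and Cohen's kappa.

#' Agreement statistics for paired angle measurements
#'
#' Differences are `method - reference`. The SD uses the sample (n - 1)
#' denominator, matching the Bland-Altman convention, and the limits of
#' agreement are `mean_diff +/- 1.96 * sd_diff`.
#'
#' @param method,reference equal-length numeric vectors of angles
#'   (degrees), length at least 2.
#' @param icc_ci compute the ICC confidence interval (needs n >= 5).
#' @return an object of class `agreement_report`: `n`, `mean_diff`,
#'   `sd_diff`, `mae`, `ba_limits` (lower, upper), `pct_within_limits`,
#'   `icc`, `icc_ci`.
#' @export
angle_agreement <- function(method, reference, icc_ci = TRUE) {
  stopifnot(length(method) == length(reference),
            all(is.finite(method)), all(is.finite(reference)))
  n <- length(method)
  if (n < 2) stop("need at least 2 paired measurements")
  d <- method - reference
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  limits <- c(lower = mean_diff - 1.96 * sd_diff,
              upper = mean_diff + 1.96 * sd_diff)
  icc <- icc_2_1(method, reference, ci = icc_ci && n >= 5)
  structure(list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff, mae = mean(abs(d)),
    ba_limits = limits,
    pct_within_limits = 100 * mean(d >= limits[1] & d <= limits[2]),
    icc = icc$icc, icc_ci = icc$ci
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  difference: %.3f +/- %.3f deg (MAE %.3f)\n",
              x$mean_diff, x$sd_diff, x$mae))
  cat(sprintf("  limits of agreement: [%.3f, %.3f] (%.2f%% within)\n",
              x$ba_limits[1], x$ba_limits[2], x$pct_within_limits))
  if (is.null(x$icc_ci) || any(is.na(x$icc_ci)))
    cat(sprintf("  ICC(2,1): %.3f\n", x$icc))
  else
    cat(sprintf("  ICC(2,1): %.3f (95%% CI %.3f-%.3f)\n",
                x$icc, x$icc_ci[1], x$icc_ci[2]))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, computed
#' from the mean-squares decomposition of the subjects x raters table
#' (here two raters: method and reference). The confidence interval uses
#' the standard F-based construction with a Satterthwaite approximation
#' for the denominator degrees of freedom. Data with zero total variance
#' define ICC = 1.
#'
#' @param method,reference equal-length numeric vectors.
#' @param ci compute the 95% confidence interval (needs n >= 5).
#' @param conf_level confidence level for the interval.
#' @return list with `icc` and `ci` (length-2 numeric or `NULL`).
#' @export
icc_2_1 <- function(method, reference, ci = TRUE, conf_level = 0.95) {
  stopifnot(length(method) == length(reference))
  x <- cbind(method, reference)
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("need at least 2 subjects")
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-12 * max(1, grand^2))
    return(list(icc = 1, ci = c(1, 1)))
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  out <- list(icc = icc, ci = NULL)
  if (ci && n >= 5) {
    alpha <- 1 - conf_level
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    out$ci <- c(lower, upper)
  }
  out
}

#' Cohen's kappa for two label sequences
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. Two constant, identical raters (`p_e = 1`) define
#' `kappa = 1`.
#'
#' @param labels_a,labels_b equal-length label vectors (e.g. Graf types
#'   `"I"`/`"II"`).
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < 1e-12) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Classification agreement report
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param levels label levels for the confusion matrix rows/columns.
#' @return an object of class `classification_report`: `agreement_rate`
#'   (percent), `kappa`, `confusion` (counts, `labels_a` in rows).
#' @export
classification_report <- function(labels_a, labels_b,
                                  levels = c("I", "II")) {
  if (length(labels_a) == 0) stop("empty input")
  stopifnot(length(labels_a) == length(labels_b))
  a <- factor(as.character(labels_a), levels = levels)
  b <- factor(as.character(labels_b), levels = levels)
  tab <- table(a, b, dnn = c("a", "b"))
  structure(list(
    agreement_rate = 100 * sum(diag(tab)) / sum(tab),
    kappa = cohen_kappa(a, b),
    confusion = tab
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Agreement rate: %.2f%%, Cohen's kappa: %.3f\n",
              x$agreement_rate, x$kappa))
  print(x$confusion)
  invisible(x)
}
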