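#' Distribution of error/uncertainty ratios
#'
#' Elementwise ratios `e / s` of absolute errors to uncertainties, with
#' summary statistics.  Items with zero uncertainty are excluded from the
#' ratios and counted, never silently dropped.
#'
#' @param errors numeric vector of absolute errors (>= 0).
#' @param uncertainties numeric vector of uncertainties (>= 0), same length.
#' @return list with `ratios`, `mean`, `median`, `iqr`, `n`, `n_excluded`.
#' @examples
#' ratio_distribution(c(0.2, 0.6, 0.4), c(0.4, 0.8, 0.5))$mean  # 0.6833...
#' @export
ratio_distribution <- function(errors, uncertainties) {
  pairs <- check_eu(errors, uncertainties)
  keep <- pairs$s > 0
  if (!any(keep)) stop_uq("all uncertainties are zero")
  r <- pairs$e[keep] / pairs$s[keep]
  list(ratios = r, mean = mean(r), median = stats::median(r),
       iqr = IQR(r), n = sum(keep), n_excluded = sum(!keep))
}

check_eu <- function(errors, uncertainties) {
  e <- as.numeric(errors); s <- as.numeric(uncertainties)
  if (length(e) != length(s)) stop_uq("errors and uncertainties differ in length")
  check_finite(e, "errors"); check_finite(s, "uncertainties")
  if (any(e < 0) || any(s < 0)) stop_uq("errors and uncertainties must be >= 0")
  list(e = e, s = s)
}

#' Fit the error/uncertainty proportionality constant alpha
#'
#' The central calibration model: aggregated absolute errors are
#' proportional to aggregated committee uncertainties, `e ~ alpha * s`,
#' with `alpha = sqrt(2 / (pi * N_C))` in the variance-only Gaussian limit
#' and larger values when model bias contributes.  `uq_calibrate()` fits
#' alpha from a (typically small) calibration set and the fitted model
#' predicts absolute errors for new uncertainties via `predict()`.  No
#' recalibration beyond this one-parameter fit is performed.
#'
#' Two fit methods are available: `"mean_ratio"` (default),
#' `alpha = mean(e / s)` over items with `s > 0`; and `"origin_slope"`,
#' the least-squares slope of `e` on `s` through the origin,
#' `alpha = sum(e * s) / sum(s^2)`.
#'
#' @param errors absolute errors (aggregated scalars), or a formula
#'   `errors ~ uncertainties` for the formula method.
#' @param uncertainties matching uncertainties; for the formula method, a
#'   data frame holding both variables.
#' @param method `"mean_ratio"` or `"origin_slope"`.
#' @param level which aggregation level the scalars live at
#'   (`"structure"`, `"local"`, or `"atomic"`); recorded, not acted on.
#' @param data data frame for the formula method.
#' @param ... passed between methods.
#' @return an object of class `uq_calibration` with components `alpha`,
#'   `method`, `n_fit`, `level`, `n_excluded` and the fitting data; it
#'   supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @examples
#' s <- runif(50, 0.02, 0.2)
#' e <- 1.2 * s * exp(rnorm(50, 0, 0.1))
#' fit <- uq_calibrate(e, s)
#' coef(fit)
#' predict(fit, c(0.05, 0.1))
#' @export
uq_calibrate <- function(errors, ...) UseMethod("uq_calibrate")

#' @rdname uq_calibrate
#' @export
uq_calibrate.default <- function(errors, uncertainties,
                                 method = c("mean_ratio", "origin_slope"),
                                 level = c("structure", "local", "atomic"),
                                 ...) {
  method <- match.arg(method)
  level <- match.arg(level)
  pairs <- check_eu(errors, uncertainties)
  keep <- pairs$s > 0
  if (sum(keep) < 2L) stop_uq("need at least 2 pairs with positive uncertainty")
  e <- pairs$e[keep]; s <- pairs$s[keep]
  alpha <- switch(method,
                  mean_ratio = mean(e / s),
                  origin_slope = sum(e * s) / sum(s * s))
  if (!is.finite(alpha) || alpha <= 0)
    stop_uq("degenerate fit: alpha = %g", alpha)
  structure(list(alpha = alpha, method = method, n_fit = sum(keep),
                 level = level, n_excluded = sum(!keep),
                 errors = e, uncertainties = s,
                 call = match.call()),
            class = "uq_calibration")
}

#' @rdname uq_calibrate
#' @export
uq_calibrate.formula <- function(errors, data, ...) {
  mf <- stats::model.frame(errors, data)
  if (ncol(mf) != 2L) stop_uq("formula must be errors ~ uncertainties")
  uq_calibrate.default(mf[[1]], mf[[2]], ...)
}

#' @export
print.uq_calibration <- function(x, ...) {
  cat(sprintf("Error/uncertainty calibration (%s level)\n", x$level))
  cat(sprintf("  alpha = %.4f  (method: %s, n = %d%s)\n", x$alpha, x$method,
              x$n_fit,
              if (x$n_excluded > 0)
                sprintf(", %d zero-uncertainty items excluded", x$n_excluded)
              else ""))
  invisible(x)
}

#' @export
coef.uq_calibration <- function(object, ...) c(alpha = object$alpha)

#' Predict absolute errors from uncertainties
#'
#' The predicted error is simply `alpha * s`, elementwise, in the units of
#' the uncertainties (eV/Angstrom for forces).
#'
#' @param object a fitted [uq_calibrate()] model.
#' @param uncertainty uncertainties to convert; defaults to the fitting set.
#' @param ... unused.
#' @return predicted absolute errors.
#' @export
predict.uq_calibration <- function(object, uncertainty = NULL, ...) {
  if (is.null(uncertainty)) uncertainty <- object$uncertainties
  uncertainty <- as.numeric(uncertainty)
  check_finite(uncertainty, "uncertainties")
  if (any(uncertainty < 0)) stop_uq("uncertainties must be >= 0")
  object$alpha * uncertainty
}

#' @export
fitted.uq_calibration <- function(object, ...) predict(object)

#' @export
residuals.uq_calibration <- function(object, ...)
  object$errors - fitted(object)

#' @export
summary.uq_calibration <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              mad = mean(abs(res)),
              mean_error = mean(object$errors),
              correlations = correlation_summary(object$errors,
                                                 object$uncertainties))
  class(out) <- "summary.uq_calibration"
  out
}

#' @export
print.summary.uq_calibration <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  fit-set mean |e|: %.4g;  MAD of alpha*s vs e: %.4g\n",
              x$mean_error, x$mad))
  cat(sprintf("  pearson %.3f, spearman %.3f\n",
              x$correlations$pearson, x$correlations$spearman))
  invisible(x)
}

#' @export
plot.uq_calibration <- function(x, ...) {
  plot(x$uncertainties, x$errors,
       xlab = "aggregated uncertainty s (eV/A)",
       ylab = "aggregated absolute error e (eV/A)",
       main = sprintf("alpha = %.3f (%s)", x$alpha, x$method), ...)
  abline(0, x$alpha, lty = 2, col = "grey40")
  invisible(x)
}

#' Pearson and Spearman correlation of errors and uncertainties
#'
#' @param errors,uncertainties numeric vectors, length >= 3.
#' @return list with `pearson` and `spearman`.
#' @export
correlation_summary <- function(errors, uncertainties) {
  pairs <- check_eu(errors, uncertainties)
  if (length(pairs$e) < 3L) stop_uq("need at least 3 pairs")
  if (sd(pairs$e) == 0 || sd(pairs$s) == 0)
    stop_uq("zero-variance input: correlation undefined")
  list(pearson = cor(pairs$e, pairs$s, method = "pearson"),
       spearman = cor(pairs$e, pairs$s, method = "spearman"))
}

#' Calibration/evaluation split
#'
#' Indices of the calibration subset: either the deterministic first
#' `ceiling(fraction * n)` items or a seeded uniform draw.
#'
#' @param n number of items.
#' @param fraction calibration fraction (default 0.2: fit alpha on 20%,
#'   evaluate on the remaining 80%).
#' @param method `"first"` (deterministic) or `"random"` (seeded).
#' @param seed RNG seed for the random method.
#' @return integer vector of calibration indices; the evaluation set is
#'   `setdiff(seq_len(n), idx)`.
#' @export
calibration_split <- function(n, fraction = 0.2,
                              method = c("first", "random"), seed = NULL) {
  method <- match.arg(method)
  k <- max(2L, ceiling(fraction * n))
  if (k >= n) stop_uq("calibration fraction leaves no evaluation items")
  if (method == "first") return(seq_len(k))
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(n, k))
}
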