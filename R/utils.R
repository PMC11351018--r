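# internal helpers: validation and small-sample std-estimator algebra

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_uq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_uq("non-finite values in %s", what)
  invisible(x)
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop_uq("shape mismatch in %s", what)
  invisible(NULL)
}

#' Bias factor of the sample standard deviation
#'
#' For `n` i.i.d. Gaussian draws, the unbiased-variance estimator `s`
#' (divisor `n - 1`) underestimates the population standard deviation:
#' `E[s] = c4(n) * sigma` with
#' `c4(n) = sqrt(2 / (n - 1)) * Gamma(n / 2) / Gamma((n - 1) / 2)`.
#' Dividing `s` by `c4(n)` makes it unbiased for `sigma`; this is the
#' optional small-sample correction of [committee_std()].
#'
#' @param n number of draws (committee members), `n >= 2`.
#' @return the bias factor, a number in (0, 1).
#' @examples
#' c4_factor(2)   # sqrt(2 / pi)
#' c4_factor(10)
#' @export
c4_factor <- function(n) {
  if (any(n < 2)) stop_uq("c4 factor requires n >= 2")
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

#' Variance-only error/uncertainty conversion factor
#'
#' For a committee of `n_c` models whose predictions are i.i.d. Gaussian
#' around the target (model variance as the only error source), the
#' expected absolute error of the committee mean is related to the
#' population spread by `sqrt(2 / (pi * n_c))`: the committee mean has
#' standard deviation `sigma / sqrt(n_c)` and the mean absolute value of a
#' centred Gaussian is `sigma * sqrt(2 / pi)`.  This is the theoretical
#' ratio of aggregated mean absolute error to mean committee standard
#' deviation in the variance-only limit (0.25 for `n_c = 10`).
#'
#' @param n_c committee size.
#' @return the dimensionless conversion factor.
#' @seealso [expected_ratio()] for the exact finite-committee expectation of
#'   the *estimated* ratio, which also accounts for the bias of the sample
#'   standard deviation.
#' @examples
#' theoretical_ratio(10)  # ~0.2523
#' @export
theoretical_ratio <- function(n_c) sqrt(2 / (pi * n_c))

#' Exact sampling expectation of the error/uncertainty ratio
#'
#' [theoretical_ratio()] relates the expected absolute error to the *true*
#' population spread.  In practice the spread is estimated by the sample
#' standard deviation `s` over `n_c` members, which is biased
#' (`E[s] = c4(n_c) * sigma`) and whose reciprocal has
#' `E[sigma / s] = sqrt((n_c - 1) / 2) * Gamma((n_c - 2) / 2) /
#' Gamma((n_c - 1) / 2)`.  The mean of *aggregated* ratios (ratio of two
#' large-sample means) therefore converges to
#' `theoretical_ratio(n_c) / c4_factor(n_c)`, while the mean of
#' *individual* per-component ratios `e / s` converges to
#' `theoretical_ratio(n_c) * E[sigma / s]` (infinite for `n_c = 2`, where
#' `1 / s` is not integrable).  Both are what a Monte Carlo experiment
#' actually measures.
#'
#' @param n_c committee size.
#' @param level `"aggregated"` (ratio of means over many components) or
#'   `"individual"` (mean of per-component ratios).
#' @return the expected ratio.
#' @examples
#' expected_ratio(10, "aggregated")  # ~0.2594
#' expected_ratio(10, "individual")  # ~0.2761
#' @export
expected_ratio <- function(n_c, level = c("aggregated", "individual")) {
  level <- match.arg(level)
  if (n_c < 2) stop_uq("committee size must be >= 2")
  if (level == "aggregated") {
    theoretical_ratio(n_c) / c4_factor(n_c)
  } else {
    if (n_c == 2) return(Inf)
    theoretical_ratio(n_c) *
      sqrt((n_c - 1) / 2) * exp(lgamma((n_c - 2) / 2) - lgamma((n_c - 1) / 2))
  }
}
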