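#' Sparsification and oracle curves
#'
#' Orders the test items by uncertainty (or, for the oracle, by the true
#' absolute error), iteratively removes the highest-ranked items, and
#' records the mean absolute error of the retained set at every removal
#' fraction.  If the uncertainties carry the same ordering information as
#' the errors the two curves coincide and the area between them is zero; a
#' large area means the uncertainties cannot rank the errors.
#'
#' At removal fraction `f` the retained set is the `ceiling((1 - f) * n)`
#' items with the smallest ranking value; ties are broken by the original
#' index (stable).  The area is the trapezoidal integral of
#' (uncertainty curve - oracle curve) over the fraction grid.
#'
#' @param errors absolute errors, length `n >= 2`.
#' @param uncertainties matching uncertainties.
#' @param n_steps number of evenly spaced removal fractions
#'   `0, 1/n_steps, ..., (n_steps - 1)/n_steps` (default 100).
#' @return an object of class `sparsification_curve`: list with
#'   `fractions_removed`, `mae_uncertainty_order`, `mae_oracle_order`,
#'   `area_between`, `n`.  Has `print` and `plot` methods.
#' @examples
#' e <- c(1, 2, 3, 4)
#' sp <- sparsification(e, e, n_steps = 4)
#' sp$area_between  # 0: uncertainties equal errors
#' @export
sparsification <- function(errors, uncertainties, n_steps = 100) {
  pairs <- check_eu(errors, uncertainties)
  n <- length(pairs$e)
  if (n < 2L) stop_uq("need at least 2 items")
  if (n_steps < 2L) stop_uq("n_steps must be >= 2")
  fractions <- (seq_len(n_steps) - 1L) / n_steps

  curve_for <- function(key) {
    ord <- order(key, seq_len(n))            # ascending, stable ties
    csum <- cumsum(pairs$e[ord])
    k <- pmax(1L, ceiling((1 - fractions) * n))
    csum[k] / k                              # MAE of the k smallest-by-key
  }
  mae_unc <- curve_for(pairs$s)
  mae_ora <- curve_for(pairs$e)
  area <- trapezoid(fractions, mae_unc - mae_ora)
  structure(list(fractions_removed = fractions,
                 mae_uncertainty_order = mae_unc,
                 mae_oracle_order = mae_ora,
                 area_between = area, n = n),
            class = "sparsification_curve")
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' @export
print.sparsification_curve <- function(x, ...) {
  cat(sprintf(paste0("Sparsification over %d items: full-set MAE %.4g,",
                     " area between curve and oracle %.4g\n"),
              x$n, x$mae_uncertainty_order[1], x$area_between))
  invisible(x)
}

#' @export
plot.sparsification_curve <- function(x, ...) {
  plot(x$fractions_removed, x$mae_uncertainty_order, type = "l",
       xlab = "fraction of data removed", ylab = "MAE of retained set (eV/A)",
       ylim = range(0, x$mae_uncertainty_order), ...)
  lines(x$fractions_removed, x$mae_oracle_order, lty = 2)
  legend("topright", legend = c("by uncertainty", "oracle (by error)"),
         lty = 1:2, bty = "n")
  invisible(x)
}
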