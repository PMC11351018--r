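#' Ground-truth spread distributions for the committee simulator
#'
#' The variance-only committee simulator assigns every force component its
#' own ground-truth spread `sigma`, drawn from one of these distributions
#' (all with strictly positive support).  `sigma_invgamma()` is the
#' default benchmark distribution (heteroscedastic, heavy-tailed);
#' `sigma_uniform()`, `sigma_normal()` (truncated at 0 by redrawing) and
#' `sigma_constant()` exist because the headline result -- concentration
#' of the aggregated error/uncertainty ratio -- is distribution-free.
#'
#' @param shape,scale inverse-Gamma shape (> 0) and scale (> 0); the
#'   defaults 3 and 1 give mean 0.5 and finite variance.
#' @param lo,hi uniform bounds, `0 < lo < hi`.
#' @param mu,sd mean and spread of the (truncated) normal.
#' @param value constant sigma, > 0.
#' @return an object of class `sigma_dist` (a list with a `draw(n)` field).
#' @name sigma_dist
#' @examples
#' d <- sigma_invgamma()
#' summary(d$draw(1000))
NULL

sigma_dist <- function(name, draw, params) {
  structure(list(name = name, draw = draw, params = params),
            class = "sigma_dist")
}

#' @rdname sigma_dist
#' @export
sigma_invgamma <- function(shape = 3, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  # 1 / Gamma(shape, rate = scale) is inverse-Gamma(shape, scale)
  sigma_dist("invgamma",
             function(n) 1 / rgamma(n, shape = shape, rate = scale),
             list(shape = shape, scale = scale))
}

#' @rdname sigma_dist
#' @export
sigma_uniform <- function(lo = 0.5, hi = 1.5) {
  stopifnot(lo > 0, hi > lo)
  sigma_dist("uniform", function(n) runif(n, lo, hi), list(lo = lo, hi = hi))
}

#' @rdname sigma_dist
#' @export
sigma_normal <- function(mu = 1, sd = 0.25) {
  stopifnot(mu > 0, sd > 0)
  sigma_dist("normal_truncated", function(n) rnorm(n, mu, sd),
             list(mu = mu, sd = sd))
}

#' @rdname sigma_dist
#' @export
sigma_constant <- function(value = 1) {
  stopifnot(value > 0)
  sigma_dist("constant", function(n) rep(value, n), list(value = value))
}

#' @export
print.sigma_dist <- function(x, ...) {
  cat(sprintf("sigma distribution: %s(%s)\n", x$name,
              paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

# Draw n strictly positive sigmas, redrawing non-positive values
# (relevant only for the truncated normal); returns draws + redraw count.
draw_sigma <- function(dist, n) {
  s <- dist$draw(n)
  redraws <- 0L
  while (any(bad <- !(is.finite(s) & s > 0))) {
    redraws <- redraws + sum(bad)
    s[bad] <- dist$draw(sum(bad))
  }
  list(sigma = s, redraws = redraws)
}

# One structure of the variance-only experiment: per component, draw sigma,
# then n_c member predictions ~ N(0, sigma); targets are identically zero,
# so the committee-mean error is |mean| and the uncertainty the unbiased
# sample std over members.  Draw order is fixed: all sigmas of the
# structure (atom index fastest, then direction), then the members of each
# component (member index fastest).
mc_structure <- function(n_c, n_j, dist) {
  m <- 3L * n_j
  sg <- draw_sigma(dist, m)
  members <- matrix(rnorm(n_c * m, 0, rep(sg$sigma, each = n_c)), nrow = n_c)
  mu <- colMeans(members)
  e <- abs(mu)
  s <- sqrt(colSums((members - rep(mu, each = n_c))^2) / (n_c - 1))
  list(e = e, s = s, sigma = sg$sigma, redraws = sg$redraws,
       members = members)
}

#' Simulate a variance-only synthetic committee
#'
#' Generates the benchmark system used to validate the error/uncertainty
#' statistics: an otherwise perfect model whose only error source is model
#' variance.  For every (structure, atom, direction) one ground-truth
#' spread `sigma` is drawn from `sigma_dist`, then `n_c` member
#' predictions are drawn i.i.d. `N(0, sigma)`; the target is identically 0.
#'
#' This returns the full member arrays and is meant for small systems (the
#' memory cost is `n_c * n_i * n_j * 3` doubles); [ratio_experiment()]
#' streams structure by structure and should be used for benchmark-scale
#' runs.
#'
#' @param n_c committee size (>= 2).
#' @param n_i number of structures.
#' @param n_j atoms per structure.
#' @param sigma_dist a [sigma_dist] object (default [sigma_invgamma()]).
#' @param seed RNG seed; fixed seed gives identical reruns.
#' @return list with `structures` (each: `committee` ([committee_forces()]),
#'   `sigma` `(N_j, 3)` matrix), `n_redraws`, and the configuration echo.
#' @export
simulate_committee <- function(n_c = 10, n_i = 1, n_j = 100,
                               sigma_dist = sigma_invgamma(), seed = NULL) {
  check_mc_config(n_c, n_i, n_j)
  if (!is.null(seed)) set.seed(seed)
  redraws <- 0L
  structures <- lapply(seq_len(n_i), function(i) {
    st <- mc_structure(n_c, n_j, sigma_dist)
    redraws <<- redraws + st$redraws
    list(committee = committee_forces(array(t(st$members), c(n_c, n_j, 3)),
                                      structure_id = sprintf("mc_%04d", i)),
         sigma = matrix(st$sigma, ncol = 3))
  })
  list(structures = structures, n_redraws = redraws,
       config = list(n_c = n_c, n_i = n_i, n_j = n_j,
                     sigma_dist = sigma_dist$name, seed = seed,
                     rng = RNGkind()[1]))
}

check_mc_config <- function(n_c, n_i, n_j) {
  if (n_c < 2) stop_uq("committee size must be >= 2")
  if (n_i < 1 || n_j < 1) stop_uq("counts must be positive")
}

#' Monte Carlo experiment: individual vs aggregated error/uncertainty ratios
#'
#' Runs the variance-only committee simulation and contrasts the ratio of
#' absolute error to committee standard deviation at two levels: per force
#' component (`individual`) and averaged within each structure over all
#' `3 * N_j` components before taking the ratio (`aggregated`).  The
#' individual ratios scatter broadly -- a single prediction is a single
#' draw -- while the aggregated ratios concentrate sharply around the
#' conversion factor `sqrt(2 / (pi * N_C))` (about 0.25 for a committee of
#' ten), which is what makes aggregated committee uncertainties
#' quantitative error predictors.
#'
#' @inheritParams simulate_committee
#' @param keep_ratios keep the raw per-component ratio vector (length
#'   `n_i * n_j * 3`) in the result?  Default `TRUE`.
#' @return an object of class `mc_ratio`: means, IQRs and standard errors
#'   of the ratios at both levels, the theoretical factor, the per-structure
#'   `e_i`, `s_i` and ratio vectors, the raw individual ratios (optional),
#'   redraw count, runtime, and the configuration echo.
#' @examples
#' r <- ratio_experiment(n_c = 10, n_i = 20, n_j = 50, seed = 1)
#' r$aggregated_ratio_mean
#' @export
ratio_experiment <- function(n_c = 10, n_i = 100, n_j = 1000,
                             sigma_dist = sigma_invgamma(), seed = NULL,
                             keep_ratios = TRUE) {
  check_mc_config(n_c, n_i, n_j)
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  e_i <- s_i <- numeric(n_i)
  ind <- if (keep_ratios) vector("list", n_i)
  ind_n <- 0
  ind_sum <- ind_sum2 <- 0
  redraws <- 0L
  for (i in seq_len(n_i)) {
    st <- mc_structure(n_c, n_j, sigma_dist)
    redraws <- redraws + st$redraws
    e_i[i] <- mean(st$e)
    s_i[i] <- mean(st$s)
    r <- st$e / st$s
    ind_n <- ind_n + length(r)
    ind_sum <- ind_sum + sum(r)
    ind_sum2 <- ind_sum2 + sum(r * r)
    if (keep_ratios) ind[[i]] <- r
  }
  agg <- e_i / s_i
  ind_mean <- ind_sum / ind_n
  ind_sd <- sqrt((ind_sum2 - ind_n * ind_mean^2) / (ind_n - 1))
  ind_all <- if (keep_ratios) unlist(ind)
  structure(list(
    individual_ratio_mean = ind_mean,
    individual_ratio_spread = if (keep_ratios) IQR(ind_all) else NA_real_,
    individual_ratio_se = ind_sd / sqrt(ind_n),
    aggregated_ratio_mean = mean(agg),
    aggregated_ratio_spread = IQR(agg),
    aggregated_ratio_se = sd(agg) / sqrt(n_i),
    theoretical_ratio = theoretical_ratio(n_c),
    e_i = e_i, s_i = s_i, aggregated_ratios = agg,
    individual_ratios = ind_all,
    n_individual = ind_n, n_redraws = redraws,
    elapsed = proc.time()[["elapsed"]] - t0,
    config = list(n_c = n_c, n_i = n_i, n_j = n_j,
                  sigma_dist = sigma_dist$name,
                  sigma_params = sigma_dist$params,
                  seed = seed, rng = RNGkind()[1])),
    class = "mc_ratio")
}

#' @export
print.mc_ratio <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Variance-only committee Monte Carlo (N_C = %d, N_i = %d, N_j = %d, sigma ~ %s)\n",
              cfg$n_c, cfg$n_i, cfg$n_j, cfg$sigma_dist))
  cat(sprintf("  individual ratio: mean %.4f, IQR %.4f  (n = %d)\n",
              x$individual_ratio_mean, x$individual_ratio_spread,
              x$n_individual))
  cat(sprintf("  aggregated ratio: mean %.4f, IQR %.4f  (n = %d)\n",
              x$aggregated_ratio_mean, x$aggregated_ratio_spread,
              cfg$n_i))
  cat(sprintf("  theoretical sqrt(2/(pi N_C)) = %.4f\n", x$theoretical_ratio))
  invisible(x)
}

#' @export
plot.mc_ratio <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  if (!is.null(x$individual_ratios))
    graphics::hist(x$individual_ratios, breaks = 60, main = "individual e/s",
                   xlab = "ratio")
  graphics::hist(x$aggregated_ratios, breaks = 30, main = "aggregated e_i/s_i",
                 xlab = "ratio")
  abline(v = x$theoretical_ratio, lty = 2)
  invisible(x)
}

#' Mean ratios as a function of committee size
#'
#' Runs one [ratio_experiment()] per committee size and tabulates the mean
#' individual and aggregated ratios next to the theoretical
#' `sqrt(2 / (pi * N_C))` curve.
#'
#' @param n_c_values committee sizes (each >= 2).
#' @inheritParams ratio_experiment
#' @return a data.frame with one row per committee size.
#' @export
ratio_vs_committee_size <- function(n_c_values = c(2, 5, 10, 50),
                                    n_i = 50, n_j = 200,
                                    sigma_dist = sigma_invgamma(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(n_c_values, function(nc) {
    r <- ratio_experiment(nc, n_i, n_j, sigma_dist, seed = NULL,
                          keep_ratios = FALSE)
    data.frame(n_c = nc,
               individual_ratio = r$individual_ratio_mean,
               aggregated_ratio = r$aggregated_ratio_mean,
               aggregated_se = r$aggregated_ratio_se,
               theoretical = r$theoretical_ratio)
  })
  do.call(rbind, rows)
}
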