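#' Committee force predictions for one structure
#'
#' Container for the `N_C x N_j x 3` block of per-member force predictions
#' of a committee of `N_C` models on a structure of `N_j` atoms, in
#' eV/Angstrom.  Member order carries no meaning and no member weighting is
#' supported; members are opaque (how they differ -- seeds, data splits --
#' is up to the user).
#'
#' @param forces a numeric array of dimension `(N_C, N_j, 3)`, or a list of
#'   `N_C` matrices of dimension `(N_j, 3)` (one per member).
#' @param structure_id optional opaque label for the structure.
#' @return an object of class `committee_forces`.
#' @examples
#' cf <- committee_forces(array(rnorm(2 * 4 * 3), c(2, 4, 3)))
#' committee_mean(cf)
#' @export
committee_forces <- function(forces, structure_id = NULL) {
  if (is.list(forces)) {
    shapes <- unique(lapply(forces, dim))
    if (length(shapes) != 1L || length(shapes[[1]]) != 2L || shapes[[1]][2] != 3L)
      stop_uq("all members must share one (N_j, 3) shape")
    forces <- aperm(simplify2array(forces), c(3, 1, 2))
  }
  if (!is.array(forces) || length(dim(forces)) != 3L || dim(forces)[3] != 3L)
    stop_uq("forces must be an (N_C, N_j, 3) array")
  if (dim(forces)[1] < 2L)
    stop_uq("a committee needs at least 2 members")
  check_finite(forces, "committee forces")
  structure(list(forces = forces,
                 n_members = dim(forces)[1],
                 n_atoms = dim(forces)[2],
                 structure_id = structure_id),
            class = "committee_forces")
}

#' @export
print.committee_forces <- function(x, ...) {
  cat(sprintf("Committee forces: %d members x %d atoms x 3 components%s\n",
              x$n_members, x$n_atoms,
              if (is.null(x$structure_id)) "" else
                sprintf("  [%s]", x$structure_id)))
  invisible(x)
}

#' Per-component field over a structure
#'
#' An `(N_j, 3)` matrix of per-component values -- a committee mean, an
#' absolute error, or a committee standard deviation.  Error and
#' uncertainty fields must be elementwise non-negative.
#'
#' @param values numeric `(N_j, 3)` matrix.
#' @param kind one of `"mean"`, `"error"`, `"uncertainty"`.
#' @return an object of class `per_component_field` (a matrix with a
#'   `kind` attribute).
#' @export
per_component_field <- function(values, kind = c("mean", "error", "uncertainty")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (ncol(values) != 3L) stop_uq("a per-component field has 3 columns")
  check_finite(values, "per-component field")
  if (kind != "mean" && any(values < 0))
    stop_uq("%s fields must be non-negative", kind)
  structure(values, kind = kind, class = c("per_component_field", "matrix"))
}

field_kind <- function(field) attr(field, "kind") %||% "mean"

#' Committee mean forces
#'
#' Elementwise arithmetic mean over the member axis: the committee's overall
#' force prediction for every atom and spatial direction.
#'
#' @param cf a [committee_forces()] object.
#' @return a [per_component_field()] of kind `"mean"`, shape `(N_j, 3)`.
#' @export
committee_mean <- function(cf) {
  stopifnot(inherits(cf, "committee_forces"))
  per_component_field(colMeans(cf$forces), "mean")
}

#' Committee standard deviation (per-component uncertainty)
#'
#' The raw uncertainty signal: for every atom and direction, the sample
#' standard deviation of the member predictions with divisor `N_C - 1`
#' (the unbiased estimator of the population *variance*).  The estimator
#' still underestimates the population standard deviation itself for small
#' committees; `small_sample_correction = TRUE` divides by [c4_factor()]
#' to remove that bias.  The correction is off by default -- downstream
#' calibration fits absorb any constant factor into alpha.
#'
#' @param cf a [committee_forces()] object with `N_C >= 2` members.
#' @param small_sample_correction divide by the `c4` std-estimator bias
#'   factor?  Default `FALSE`.
#' @return a [per_component_field()] of kind `"uncertainty"`.
#' @examples
#' cf <- committee_forces(array(c(0, 1, 2), c(3, 1, 3)))
#' committee_std(cf)  # 1 everywhere (variance (1 + 0 + 1) / 2)
#' @export
committee_std <- function(cf, small_sample_correction = FALSE) {
  stopifnot(inherits(cf, "committee_forces"))
  f <- cf$forces
  nc <- dim(f)[1]
  m <- colMeans(f)
  dev2 <- (f - rep(m, each = nc))^2
  s <- sqrt(colSums(matrix(dev2, nrow = nc)) / (nc - 1))
  s <- matrix(s, ncol = 3L)
  if (small_sample_correction) s <- s / c4_factor(nc)
  per_component_field(s, "uncertainty")
}

#' Per-component absolute force error
#'
#' Elementwise absolute difference between the committee mean prediction
#' and the reference (e.g. ab initio) forces.
#'
#' @param mean a [per_component_field()] of kind `"mean"` (or any
#'   `(N_j, 3)` matrix of predictions).
#' @param ref reference forces, an `(N_j, 3)` matrix in eV/Angstrom.
#' @return a [per_component_field()] of kind `"error"`.
#' @export
component_error <- function(mean, ref) {
  mean <- as.matrix(mean); ref <- as.matrix(ref)
  check_finite(ref, "reference forces")
  check_same_shape(mean, ref, "component_error (prediction vs reference)")
  per_component_field(abs(mean - ref), "error")
}
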