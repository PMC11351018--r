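#' Atomic configuration
#'
#' Species, Cartesian positions, lattice and periodicity flags for one
#' structure.  Positions and cell are in Angstrom; the cell is a 3x3 matrix
#' whose *rows* are the lattice vectors (so Cartesian = fractional %*% cell).
#'
#' @param species character vector of element symbols, length `N_j`.
#' @param positions numeric `(N_j, 3)` matrix of Cartesian coordinates.
#' @param cell 3x3 lattice matrix (rows = lattice vectors), or `NULL` for an
#'   isolated system.
#' @param pbc logical periodicity flags, recycled to length 3.
#' @return an object of class `atomic_configuration`.
#' @export
atomic_configuration <- function(species, positions, cell = NULL,
                                 pbc = !is.null(cell)) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop_uq("positions must be (N_j, 3)")
  if (nrow(positions) < 1L) stop_uq("need at least one atom")
  if (length(species) != nrow(positions))
    stop_uq("species and positions disagree on the number of atoms")
  check_finite(positions, "positions")
  pbc <- rep_len(as.logical(pbc), 3L)
  if (any(pbc)) {
    if (is.null(cell)) stop_uq("periodic directions require a cell")
    cell <- as.matrix(cell)
    if (!identical(dim(cell), c(3L, 3L))) stop_uq("cell must be 3x3")
    check_finite(cell, "cell")
    if (abs(det(cell)) < 1e-10) stop_uq("cell is singular")
  }
  structure(list(species = as.character(species), positions = positions,
                 cell = if (is.null(cell)) NULL else as.matrix(cell),
                 pbc = pbc),
            class = "atomic_configuration")
}

#' @export
print.atomic_configuration <- function(x, ...) {
  cat(sprintf("Atomic configuration: %d atoms (%s), pbc %s\n",
              nrow(x$positions),
              paste(names(sort(-table(x$species))), collapse = ", "),
              paste(ifelse(x$pbc, "T", "F"), collapse = " ")))
  invisible(x)
}

n_atoms <- function(config) nrow(config$positions)

# Perpendicular widths of the cell along each lattice direction:
# width_i = |det(cell)| / area of the face spanned by the other two vectors.
cell_widths <- function(cell) {
  v <- abs(det(cell))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  areas <- c(sqrt(sum(cr(cell[2, ], cell[3, ])^2)),
             sqrt(sum(cr(cell[3, ], cell[1, ])^2)),
             sqrt(sum(cr(cell[1, ], cell[2, ])^2)))
  v / areas
}

# Pairwise distances honoring mixed periodic/non-periodic directions.
# Non-periodic: plain Euclidean.  Periodic: nearest-image distance, computed
# by wrapping fractional separations into [-1/2, 1/2) and, unless the cell is
# orthogonal (where per-axis wrapping is already exact), scanning the
# surrounding replica shifts {-1, 0, 1} per periodic direction.
pairwise_distances <- function(config, exact = NULL) {
  x <- config$positions
  if (!any(config$pbc)) {
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- NULL
    return(d)
  }
  cell <- config$cell
  per <- config$pbc
  frac <- x %*% solve(cell)
  df <- lapply(1:3, function(k) outer(frac[, k], frac[, k], "-"))
  for (k in which(per)) df[[k]] <- df[[k]] - round(df[[k]])
  orthogonal <- max(abs(cell[lower.tri(cell) | upper.tri(cell)])) < 1e-10
  if (is.null(exact)) exact <- !orthogonal
  shifts <- if (exact) {
    as.matrix(expand.grid(lapply(1:3, function(k) if (per[k]) -1:1 else 0)))
  } else {
    matrix(0, 1, 3)
  }
  d2 <- NULL
  for (r in seq_len(nrow(shifts))) {
    s <- shifts[r, ]
    cart2 <- 0
    for (kk in 1:3) {
      g1 <- df[[1]] + s[1]; g2 <- df[[2]] + s[2]; g3 <- df[[3]] + s[3]
      ck <- g1 * cell[1, kk] + g2 * cell[2, kk] + g3 * cell[3, kk]
      cart2 <- cart2 + ck * ck
    }
    d2 <- if (is.null(d2)) cart2 else pmin(d2, cart2)
  }
  sqrt(d2)
}

#' Neighbor shells within a cutoff radius
#'
#' For every atom `j`, the indices of all atoms `n` whose distance to `j`
#' is at most `r_cut` (inclusive boundary), *including `j` itself*, so every
#' shell is non-empty and `r_cut = 0` yields the self-shell.  Distances are
#' Euclidean along non-periodic directions and nearest-image along periodic
#' ones.  If `r_cut` exceeds half the shortest periodic cell width the
#' nearest image is ambiguous for the single-wrap metric; a warning is
#' emitted and an explicit periodic-replica scan is used so the distances
#' remain exact.
#'
#' @param config an [atomic_configuration()].
#' @param r_cut cutoff radius in Angstrom, `> 0` (the default 4 A is the
#'   aggregation radius used for active learning).
#' @return an object of class `neighbor_shells`: a list with `neighbors`
#'   (list of sorted integer vectors), `counts`, `r_cut`.
#' @export
build_neighbor_shells <- function(config, r_cut = 4) {
  stopifnot(inherits(config, "atomic_configuration"))
  if (!is.finite(r_cut) || r_cut < 0) stop_uq("r_cut must be >= 0")
  exact <- NULL
  if (any(config$pbc)) {
    w <- cell_widths(config$cell)[config$pbc]
    if (r_cut > min(w) / 2 + 1e-9) {
      warning(sprintf(paste0("r_cut = %g exceeds half the shortest periodic",
                             " cell width (%g); falling back to an explicit",
                             " replica search"), r_cut, min(w)),
              call. = FALSE)
      exact <- TRUE
    }
  }
  d <- pairwise_distances(config, exact = exact)
  neighbors <- lapply(seq_len(nrow(d)), function(j) which(d[j, ] <= r_cut))
  structure(list(neighbors = neighbors,
                 counts = lengths(neighbors),
                 r_cut = r_cut),
            class = "neighbor_shells")
}

#' @export
print.neighbor_shells <- function(x, ...) {
  cat(sprintf("Neighbor shells: %d atoms, r_cut = %g A, N_n in [%d, %d]\n",
              length(x$neighbors), x$r_cut, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Per-atom scalar from a per-component field
#'
#' Collapses the three spatial directions of each atom to one number.  The
#' default `sum` matches the per-atom visualization convention; `mean` is
#' the convention used inside local and per-structure aggregation.
#'
#' @param field a [per_component_field()] or `(N_j, 3)` matrix.
#' @param mode `"sum"` (default) or `"mean"` over the 3 directions.
#' @return numeric vector of length `N_j`.
#' @export
per_atom_scalar <- function(field, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  field <- as.matrix(field)
  if (mode == "sum") rowSums(field) else rowMeans(field)
}

#' Per-structure aggregate
#'
#' The mean over all `3 * N_j` components of the field: for an error field
#' this is the structure's force mean absolute error `e_i`, for an
#' uncertainty field the mean committee standard deviation `s_i`.
#'
#' @param field a [per_component_field()] or `(N_j, 3)` matrix.
#' @return a scalar, eV/Angstrom.
#' @export
structure_aggregate <- function(field) mean(as.matrix(field))

#' Locally aggregated field over neighbor shells
#'
#' For every atom `j`, the mean of the field over the `3 * N_n` components
#' of all atoms in its shell (within `r_cut`, including `j`).  All shell
#' atoms are weighted equally -- no distance kernel.  Instead of one scalar
#' per structure this yields `N_j` local values, each centred on an atom;
#' for `r_cut` at least the maximum pairwise distance every local value
#' equals [structure_aggregate()].
#'
#' @param field a [per_component_field()] or `(N_j, 3)` matrix.
#' @param shells a [build_neighbor_shells()] result for the same structure.
#' @return numeric vector of length `N_j` of local aggregates.
#' @export
local_aggregate <- function(field, shells) {
  stopifnot(inherits(shells, "neighbor_shells"))
  field <- as.matrix(field)
  if (nrow(field) != length(shells$neighbors))
    stop_uq("field and shells disagree on the number of atoms")
  ps <- rowSums(field)
  vapply(shells$neighbors, function(ix) sum(ps[ix]) / (3 * length(ix)),
         numeric(1))
}

#' Uncertainty (or error) field with all aggregation levels
#'
#' Convenience constructor computing, from a per-component field, the
#' per-atom scalars (sum over directions), the local aggregates at `r_cut`
#' (if a configuration is given) and the per-structure aggregate.
#'
#' @param field a [per_component_field()] or `(N_j, 3)` matrix.
#' @param config an [atomic_configuration()] for the same structure, or
#'   `NULL` to skip local aggregation.
#' @param r_cut local aggregation radius in Angstrom (default 4).
#' @param shells optionally, precomputed [build_neighbor_shells()] (then
#'   `config`/`r_cut` are ignored for the neighbor search).
#' @return an object of class `uq_field`: list with `per_component`,
#'   `per_atom`, `local` (or `NULL`), `per_structure`, `r_cut`, `kind`.
#' @export
uncertainty_field <- function(field, config = NULL, r_cut = 4, shells = NULL) {
  field <- as.matrix(field)
  if (is.null(shells) && !is.null(config))
    shells <- build_neighbor_shells(config, r_cut)
  structure(list(per_component = field,
                 per_atom = per_atom_scalar(field, "sum"),
                 local = if (is.null(shells)) NULL
                         else local_aggregate(field, shells),
                 per_structure = structure_aggregate(field),
                 r_cut = if (is.null(shells)) NA_real_ else shells$r_cut,
                 kind = field_kind(field)),
            class = "uq_field")
}

#' @export
print.uq_field <- function(x, ...) {
  cat(sprintf("%s field: %d atoms, per-structure %.6g eV/A%s\n",
              x$kind, nrow(x$per_component), x$per_structure,
              if (is.null(x$local)) "" else
                sprintf(", local at r_cut = %g A", x$r_cut)))
  invisible(x)
}

#' Atom with the maximum local uncertainty
#'
#' Argmax over the local aggregates; ties are broken towards the lowest
#' atom index.  The maximum local uncertainty of a structure tracks its
#' overall mean absolute error, so it doubles as a frame score in active
#' learning.
#'
#' @param field a `uq_field` with local values, or a numeric vector of
#'   local values.
#' @return list with `atom` (index) and `value`.
#' @export
max_local_uncertainty <- function(field) {
  local <- if (inherits(field, "uq_field")) field$local else as.numeric(field)
  if (is.null(local)) stop_uq("no local values: aggregate with a configuration first")
  j <- which.max(local)
  list(atom = j, value = local[j])
}

#' Per-atom field table
#'
#' Flattens aggregation results into the tabular form used for CSV export:
#' one row per atom with its per-atom and local values.
#'
#' @param field a `uq_field` as returned by [uncertainty_field()].
#' @param structure_id optional id column value.
#' @return a data.frame with columns `structure_id`, `atom_index`,
#'   `per_atom`, `local`, `r_cut`.
#' @export
field_table <- function(field, structure_id = NA) {
  stopifnot(inherits(field, "uq_field"))
  data.frame(structure_id = structure_id,
             atom_index = seq_along(field$per_atom),
             per_atom = field$per_atom,
             local = field$local %||% NA_real_,
             r_cut = field$r_cut)
}
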