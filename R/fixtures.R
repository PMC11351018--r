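#' Synthetic committee archive generator
#'
#' Builds a reproducible archive of random periodic structures with
#' committee force predictions drawn around a smooth ground-truth force
#' field, for testing and benchmarking the whole pipeline without
#' training any models.  Per component the member predictions are
#' `truth + N(0, sigma)`; the per-component spread `sigma` is a constant
#' background, optionally multiplied inside a spherical *variance
#' hot-spot* (emulating a locally poorly-learned region), and an optional
#' additive *bias* shifts every member identically inside the hot-spot
#' (error invisible to the committee spread, emulating model bias).
#' Reference forces are the exact ground truth.
#'
#' The ground-truth field is a smooth periodic function of position,
#' `F_k(r) = amplitude * sin(2 pi r_{k'} / L)` with `k'` the next
#' direction, so forces vary over the box but are reproducible.
#'
#' @param n_structures number of structures.
#' @param n_atoms atoms per structure.
#' @param n_members committee size (default 5, a typical trained
#'   ensemble).
#' @param box_length cubic cell edge in Angstrom.
#' @param sigma0 background per-component spread, eV/A.
#' @param amplitude ground-truth force amplitude, eV/A.
#' @param species element label for all atoms.
#' @param hotspot `NULL`, or a list with `radius` (A), `factor`
#'   (multiplier on sigma inside the spot, > 1 for a variance hot-spot)
#'   and optional `bias` (additive member shift, eV/A); the hot-spot
#'   center is drawn uniformly per structure and recorded.
#' @param seed RNG seed; fixed seed gives an identical archive.
#' @return an object of class `committee_archive`: a list of structures,
#'   each with `structure_id`, `config`, `committee`, `reference`,
#'   `sigma` (the `(N_j, 3)` truth spread), `hot_atoms` (indices inside
#'   the hot-spot, or `integer(0)`); plus attributes `seed`, `units`.
#' @export
make_fixtures <- function(n_structures = 4, n_atoms = 100, n_members = 5,
                          box_length = 10, sigma0 = 0.05, amplitude = 1,
                          species = "Ar", hotspot = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structures <- lapply(seq_len(n_structures), function(i) {
    pos <- matrix(runif(n_atoms * 3, 0, box_length), n_atoms, 3)
    config <- atomic_configuration(rep(species, n_atoms), pos,
                                   cell = diag(3) * box_length, pbc = TRUE)
    truth <- amplitude * sin(2 * pi * pos[, c(2, 3, 1)] / box_length)
    sigma <- matrix(sigma0, n_atoms, 3)
    bias <- matrix(0, n_atoms, 3)
    hot_atoms <- integer(0)
    if (!is.null(hotspot)) {
      centre <- runif(3, 0, box_length)
      d <- pos - matrix(centre, n_atoms, 3, byrow = TRUE)
      d <- d - box_length * round(d / box_length)
      hot_atoms <- which(sqrt(rowSums(d^2)) <= hotspot$radius)
      sigma[hot_atoms, ] <- sigma0 * (hotspot$factor %||% 1)
      if (!is.null(hotspot$bias))
        bias[hot_atoms, ] <- hotspot$bias
    }
    members <- lapply(seq_len(n_members), function(l)
      truth + bias + matrix(rnorm(n_atoms * 3, 0, sigma), n_atoms, 3))
    list(structure_id = sprintf("fix_%04d", i),
         config = config,
         committee = committee_forces(members,
                                      structure_id = sprintf("fix_%04d", i)),
         reference = truth,
         sigma = sigma,
         hot_atoms = hot_atoms)
  })
  structure(structures, seed = seed, units = "eV/Angstrom",
            class = "committee_archive")
}

#' @export
print.committee_archive <- function(x, ...) {
  cat(sprintf("Committee archive: %d structures, %d members x %d atoms\n",
              length(x), x[[1]]$committee$n_members,
              x[[1]]$committee$n_atoms))
  invisible(x)
}

#' Write/read a committee archive as extended-XYZ
#'
#' Serializes each structure with per-member columns `forces_0..` and
#' reference column `forces_ref`; `read_committee_archive()` restores the
#' committee and reference per frame.
#'
#' @param archive a [make_fixtures()] result (or compatible list).
#' @param path file path.
#' @return `write_committee_archive()`: `path`;
#'   `read_committee_archive()`: list of structures with `structure_id`,
#'   `config`, `committee`, `reference`.
#' @export
write_committee_archive <- function(archive, path) {
  frames <- lapply(archive, function(st) {
    arrays <- setNames(
      lapply(seq_len(st$committee$n_members),
             function(l) st$committee$forces[l, , ]),
      sprintf("forces_%d", seq_len(st$committee$n_members) - 1L))
    arrays$forces_ref <- st$reference
    list(config = st$config, arrays = arrays,
         info = list(structure_id = st$structure_id))
  })
  write_extxyz(frames, path, comment = "forceuq committee archive")
}

#' @rdname write_committee_archive
#' @export
read_committee_archive <- function(path) {
  frames <- read_extxyz(path)
  lapply(frames, function(fr)
    list(structure_id = fr$info$structure_id,
         config = fr$config,
         committee = committee_from_frame(fr),
         reference = reference_from_frame(fr)))
}

# place two companions at bond length around each center with a fixed
# bond angle and a random orientation
water_hydrogens <- function(o_pos, bond = 0.97, angle = 104.5 * pi / 180) {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  h1 <- o_pos + bond * u
  h2 <- o_pos + bond * (cos(angle) * u + sin(angle) * v)
  rbind(h1, h2)
}

#' Synthetic water-like periodic box
#'
#' Places `n_molecules` oxygen atoms at random positions with a minimum
#' O--O separation (simple rejection), attaches two hydrogens per oxygen
#' at 0.97 A with the water bond angle and a random orientation, and wraps
#' everything into a cubic periodic cell -- so some molecules straddle the
#' boundary, which is exactly what the subbox-extraction unwrapping must
#' handle.  Atom order is all oxygens first, then the hydrogen pairs in
#' oxygen order.
#'
#' @param n_molecules number of water molecules.
#' @param box_length cubic edge in Angstrom; default gives roughly liquid
#'   density (30 A^3 per molecule).
#' @param min_oo minimum O--O separation for the rejection sampler, A.
#' @param seed RNG seed.
#' @return an [atomic_configuration()] of `3 * n_molecules` atoms with a
#'   `molecule` attribute mapping each atom to its molecule index.
#' @export
synthetic_water_box <- function(n_molecules = 128, box_length = NULL,
                                min_oo = 2.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  box_length <- box_length %||% (30 * n_molecules)^(1 / 3)
  o <- matrix(NA_real_, n_molecules, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n_molecules) {
    tries <- tries + 1L
    if (tries > 2e5) stop_uq("cannot place %d molecules at min O-O %g A",
                             n_molecules, min_oo)
    cand <- runif(3, 0, box_length)
    if (placed > 0L) {
      d <- o[seq_len(placed), , drop = FALSE] -
        matrix(cand, placed, 3, byrow = TRUE)
      d <- d - box_length * round(d / box_length)
      if (min(rowSums(d^2)) < min_oo^2) next
    }
    placed <- placed + 1L
    o[placed, ] <- cand
  }
  h <- do.call(rbind, lapply(seq_len(n_molecules),
                             function(i) water_hydrogens(o[i, ])))
  pos <- rbind(o, h)
  dimnames(pos) <- NULL
  pos <- pos - box_length * floor(pos / box_length)   # wrap into the cell
  cfg <- atomic_configuration(c(rep("O", n_molecules),
                                rep("H", 2 * n_molecules)),
                              pos, cell = diag(3) * box_length, pbc = TRUE)
  attr(cfg, "molecule") <- c(seq_len(n_molecules),
                             rep(seq_len(n_molecules), each = 2))
  cfg
}
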