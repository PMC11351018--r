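# Independent oracles and small generators used across the suite.

# Brute-force neighbor shells: explicit replica positions over all shift
# combinations (no fractional wrapping), the reference for the minimum-image
# search.
oracle_shells <- function(config, r_cut) {
  x <- config$positions
  n <- nrow(x)
  shifts <- as.matrix(expand.grid(lapply(1:3, function(k)
    if (config$pbc[k]) -1:1 else 0)))
  images <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(r) {
    off <- as.numeric(shifts[r, ] %*% config$cell)
    x + matrix(off, n, 3, byrow = TRUE)
  }))
  idx <- rep(seq_len(n), nrow(shifts))
  lapply(seq_len(n), function(j) {
    d <- sqrt(rowSums((images - matrix(x[j, ], nrow(images), 3,
                                       byrow = TRUE))^2))
    sort(unique(idx[d <= r_cut]))
  })
}

random_periodic_config <- function(n, triclinic = FALSE) {
  L <- runif(3, 6, 12)
  cell <- diag(L)
  if (triclinic) {
    cell[2, 1] <- runif(1, -2, 2)
    cell[3, 1] <- runif(1, -2, 2)
    cell[3, 2] <- runif(1, -2, 2)
  }
  frac <- matrix(runif(n * 3), n, 3)
  atomic_configuration(rep("X", n), frac %*% cell, cell, TRUE)
}

# Harmonic calculator: springs of stiffness k pulling every atom towards a
# target offset from the box centre (translation with the cell, so staged
# re-centring does not fight the springs).
harmonic_calculator <- function(target_offsets, k = 1) {
  force(target_offsets); force(k)
  function(cfg) {
    centre <- cfg$cell[1, 1] / 2
    dx <- cfg$positions - centre - target_offsets
    list(energy = 0.5 * k * sum(dx^2), forces = -k * dx)
  }
}

zero_calculator <- function(cfg)
  list(energy = 0, forces = matrix(0, nrow(cfg$positions), 3))

# Uniform-field trajectory with one planted high-uncertainty atom in one
# frame per segment; returns the trajectory and the planted (frame, atom)
# pairs.
planted_trajectory <- function(n_frames = 20, n_segments = 10, n_atoms = 40,
                               box = 10, base = 0.01, spike = 1) {
  cfg <- atomic_configuration(rep("X", n_atoms),
                              matrix(runif(n_atoms * 3, 0, box), n_atoms, 3),
                              diag(3) * box, TRUE)
  per_seg <- n_frames %/% n_segments
  frames <- sapply(seq_len(n_segments), function(s)
    (s - 1L) * per_seg + sample.int(per_seg, 1L))
  atoms <- sample.int(n_atoms, n_segments, replace = TRUE)
  fields <- lapply(seq_len(n_frames), function(t) {
    f <- matrix(base, n_atoms, 3)
    hit <- which(frames == t)
    if (length(hit)) f[atoms[hit[1]], ] <- spike
    f
  })
  list(traj = trajectory_uncertainty(rep(list(cfg), n_frames), fields),
       frames = frames, atoms = atoms)
}
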