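#' Trajectory with per-frame uncertainty fields
#'
#' Container pairing each frame of an MD trajectory with the per-component
#' uncertainty field of its committee prediction.  Frames must be
#' time-ordered and share one atom count.
#'
#' @param configs list of [atomic_configuration()] frames.
#' @param fields list of matching `(N_j, 3)` per-component uncertainty
#'   matrices (or [per_component_field()]s).
#' @param times optional frame times; defaults to the frame index.
#' @return an object of class `uq_trajectory`.
#' @export
trajectory_uncertainty <- function(configs, fields, times = NULL) {
  if (length(configs) != length(fields))
    stop_uq("configs and fields differ in length")
  n <- vapply(configs, n_atoms, 0L)
  if (length(unique(n)) != 1L)
    stop_uq("all frames must share one atom count")
  for (f in fields) check_same_shape(as.matrix(f),
                                     matrix(0, n[1], 3), "trajectory fields")
  times <- times %||% seq_along(configs)
  if (is.unsorted(times)) stop_uq("frames must be time-ordered")
  structure(list(configs = configs, fields = lapply(fields, as.matrix),
                 times = times, n_frames = length(configs),
                 n_atoms = n[1]),
            class = "uq_trajectory")
}

#' @export
print.uq_trajectory <- function(x, ...) {
  cat(sprintf("Uncertainty trajectory: %d frames x %d atoms\n",
              x$n_frames, x$n_atoms))
  invisible(x)
}

segment_bounds <- function(n_frames, n_segments) {
  # even partition of the frame range; the remainder goes to the last segment
  base <- n_frames %/% n_segments
  sizes <- rep(base, n_segments)
  sizes[n_segments] <- n_frames - base * (n_segments - 1L)
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1) + 1L), end = ends)
}

#' Segment-wise selection of high-uncertainty frames and center atoms
#'
#' Divides the trajectory into `n_segments` evenly sized segments (so new
#' structures are sampled from different intervals of the simulation) and
#' picks exactly one (frame, center atom) pair per segment:
#' \describe{
#'   \item{`local_uncertainty`}{the frame whose maximum locally aggregated
#'     uncertainty (within `r_cut`, over eligible center atoms) is largest;
#'     the center is that argmax atom.}
#'   \item{`atomic_uncertainty`}{as above but scored by the per-atom
#'     uncertainty (sum over the three directions), unaggregated.}
#'   \item{`random`}{a seeded uniform frame and eligible center atom.}
#' }
#' Ties go to the earliest frame and lowest atom index.
#'
#' @param traj a [trajectory_uncertainty()] object.
#' @param n_segments number of segments (default 10).
#' @param strategy selection strategy; see above.
#' @param r_cut local aggregation radius (Angstrom) for
#'   `local_uncertainty` (default 4).
#' @param species optional species filter: only atoms of these species are
#'   eligible centers (e.g. `"O"` to center on oxygens).
#' @param seed RNG seed for the random strategy.
#' @return an object of class `selection_plan`: a data.frame with columns
#'   `segment`, `frame`, `center`, `score`, plus attributes `strategy`,
#'   `r_cut`, `seed`.
#' @export
select_frames <- function(traj, n_segments = 10,
                          strategy = c("local_uncertainty",
                                       "atomic_uncertainty", "random"),
                          r_cut = 4, species = NULL, seed = NULL) {
  stopifnot(inherits(traj, "uq_trajectory"))
  strategy <- match.arg(strategy)
  if (traj$n_frames < n_segments)
    stop_uq("fewer frames (%d) than segments (%d)", traj$n_frames, n_segments)
  eligible <- if (is.null(species)) seq_len(traj$n_atoms)
              else which(traj$configs[[1]]$species %in% species)
  if (length(eligible) == 0L) stop_uq("no atoms match the species filter")
  if (!is.null(seed)) set.seed(seed)

  atom_scores <- function(t) {
    switch(strategy,
      local_uncertainty = {
        shells <- build_neighbor_shells(traj$configs[[t]], r_cut)
        local_aggregate(traj$fields[[t]], shells)
      },
      atomic_uncertainty = per_atom_scalar(traj$fields[[t]], "sum"))
  }

  rows <- lapply(seq_len(n_segments), function(seg) {
    b <- segment_bounds(traj$n_frames, n_segments)[seg, ]
    frames <- b[["start"]]:b[["end"]]
    if (strategy == "random") {
      fr <- frames[sample.int(length(frames), 1L)]
      ct <- eligible[sample.int(length(eligible), 1L)]
      return(data.frame(segment = seg, frame = fr, center = ct,
                        score = NA_real_))
    }
    sc <- lapply(frames, atom_scores)
    best <- vapply(sc, function(v) max(v[eligible]), 0)
    fr <- which.max(best)                       # stable: earliest frame
    v <- sc[[fr]]
    ct <- eligible[which.max(v[eligible])]      # stable: lowest index
    data.frame(segment = seg, frame = frames[fr], center = ct,
               score = best[fr])
  })
  plan <- do.call(rbind, rows)
  structure(plan, strategy = strategy, r_cut = r_cut, seed = seed,
            class = c("selection_plan", "data.frame"))
}

# Nearest-image displacement vectors from atom `from` to atoms `idx`.
mic_displacement <- function(config, from, idx) {
  d <- config$positions[idx, , drop = FALSE] -
    matrix(config$positions[from, ], length(idx), 3, byrow = TRUE)
  if (any(config$pbc)) {
    f <- d %*% solve(config$cell)
    for (k in which(config$pbc)) f[, k] <- f[, k] - round(f[, k])
    d <- f %*% config$cell
  }
  d
}

mic_distance <- function(config, from, idx)
  sqrt(rowSums(mic_displacement(config, from, idx)^2))

is_cubic <- function(config) {
  cl <- config$cell
  !is.null(cl) && all(config$pbc) &&
    max(abs(cl[lower.tri(cl) | upper.tri(cl)])) < 1e-8 &&
    diff(range(diag(cl))) < 1e-8
}

#' Cut a density-preserving subbox around a center atom
#'
#' Extracts, from a cubic periodic configuration, the center atom plus the
#' `n_center_species - 1` nearest atoms of the same species (nearest-image
#' metric) and, per kept center-species atom, its `companions` nearest
#' companion atoms (e.g. the two hydrogens of each water oxygen).
#' Companion assignment is greedy nearest-first with exclusivity: each
#' companion belongs to exactly one center-species atom.  All selected
#' atoms are unwrapped (centers to the image nearest the center atom,
#' companions to the image nearest their assigned center-species atom), so
#' molecules straddling the periodic boundary come out intact, and the
#' whole selection is translated so the center atom sits at the middle of
#' a new cubic cell of edge `l_new`.
#'
#' The default edge preserves the source density:
#' `l_new = l_orig * (N_kept / N_orig)^(1/3)`.
#'
#' @param config a cubic, fully periodic [atomic_configuration()].
#' @param center index of the center atom (must be of the center species).
#' @param n_center_species how many center-species atoms to keep
#'   (default 64).
#' @param companions companion atoms to attach per kept center-species atom
#'   (default 2); 0 for monatomic systems.
#' @param companion_species species eligible as companions; default: all
#'   species other than the center's.
#' @param l_new edge of the new cubic cell; default density-preserving.
#' @return an [atomic_configuration()] with attributes `source_indices`
#'   (mapping into `config`), `center_index` (position of the center atom
#'   in the output) and `l_new`.
#' @export
extract_subbox <- function(config, center, n_center_species = 64,
                           companions = 2, companion_species = NULL,
                           l_new = NULL) {
  stopifnot(inherits(config, "atomic_configuration"))
  if (!is_cubic(config))
    stop_uq("subbox extraction requires a cubic, fully periodic cell")
  l_orig <- config$cell[1, 1]
  cs <- config$species[center]
  same <- which(config$species == cs)
  if (length(same) < n_center_species)
    stop_uq("requested %d %s atoms but only %d available",
            n_center_species, cs, length(same))
  d <- mic_distance(config, center, same)
  keep_centers <- same[order(d, same)][seq_len(n_center_species)]

  comp_assign <- integer(0)
  comp_owner <- integer(0)
  if (companions > 0L) {
    comp_pool <- if (is.null(companion_species))
      which(config$species != cs)
    else which(config$species %in% companion_species)
    if (length(comp_pool) < companions * n_center_species)
      stop_uq("companion shortage: need %d, have %d",
              companions * n_center_species, length(comp_pool))
    dm <- vapply(keep_centers,
                 function(j) mic_distance(config, j, comp_pool),
                 numeric(length(comp_pool)))          # (pool x centers)
    ord <- order(dm)                                  # global nearest-first
    need <- rep(companions, n_center_species)
    taken <- logical(length(comp_pool))
    owner <- integer(length(comp_pool))
    for (p in ord) {
      ci <- ((p - 1L) %/% length(comp_pool)) + 1L     # center column
      pi <- ((p - 1L) %% length(comp_pool)) + 1L      # pool row
      if (need[ci] > 0L && !taken[pi]) {
        taken[pi] <- TRUE
        owner[pi] <- ci
        need[ci] <- need[ci] - 1L
      }
      if (!any(need > 0L)) break
    }
    if (any(need > 0L))
      stop_uq("companion shortage for center-species atom(s) %s",
              paste(keep_centers[need > 0L], collapse = ", "))
    comp_assign <- comp_pool[taken]
    comp_owner <- owner[taken]
    grp <- order(comp_owner, comp_assign)   # group companions by owner
    comp_assign <- comp_assign[grp]
    comp_owner <- comp_owner[grp]
  }

  # unwrap: centers relative to the central atom, companions relative to
  # their owner, guaranteeing intact molecules
  center_rel <- mic_displacement(config, center, keep_centers)
  pos <- center_rel
  src <- keep_centers
  if (companions > 0L) {
    comp_rel <- mic_displacement(config, center, comp_assign)  # placeholder
    for (q in seq_along(comp_assign)) {
      own <- keep_centers[comp_owner[q]]
      comp_rel[q, ] <- center_rel[comp_owner[q], ] +
        mic_displacement(config, own, comp_assign[q])
    }
    pos <- rbind(pos, comp_rel)
    src <- c(src, comp_assign)
  }

  n_kept <- length(src)
  if (is.null(l_new))
    l_new <- l_orig * (n_kept / n_atoms(config))^(1 / 3)
  pos <- pos + matrix(l_new / 2, n_kept, 3)
  out <- atomic_configuration(config$species[src], pos,
                              cell = diag(3) * l_new, pbc = TRUE)
  attr(out, "source_indices") <- src
  attr(out, "center_index") <- 1L
  attr(out, "l_new") <- l_new
  out
}

#' Staged border relaxation of a cut subbox
#'
#' Cutting a subbox out of a larger periodic configuration leaves
#' unphysical contacts across the new boundary.  This implements the
#' staged protocol that heals them: atoms within `fixed_core_factor *
#' l_new / 2` of the center atom are frozen; the cell is padded by `pad`
#' Angstrom; then, repeatedly, `steps_per_stage` quasi-Newton (L-BFGS)
#' iterations relax the free atoms and the cell shrinks by `shrink`
#' Angstrom, until the original edge `l_new` is recovered (so
#' `pad / shrink` stages; 10 for the defaults).  The center atom stays at
#' the middle of the box throughout and frozen atoms never move.
#'
#' @param config the cut subbox (cubic periodic [atomic_configuration()],
#'   as produced by [extract_subbox()]; positions are taken as unwrapped).
#' @param center index of the center atom in `config`.
#' @param calculator a function `function(config)` returning
#'   `list(energy = <scalar eV>, forces = <(N, 3) eV/A matrix>)`.
#' @param fixed_core_factor core radius as a fraction of `l_new / 2`
#'   (default 0.8).
#' @param pad initial padding per direction, Angstrom (default 2).
#' @param shrink edge reduction per stage, Angstrom (default 0.2).
#' @param steps_per_stage quasi-Newton iterations per stage (default 5;
#'   a fixed count, not a convergence criterion).
#' @return list with `config` (relaxed, edge restored to `l_new`),
#'   `energy_log` (data.frame: stage, edge, energy), `n_stages`, `frozen`
#'   (indices).
#' @export
relax_border <- function(config, center, calculator,
                         fixed_core_factor = 0.8, pad = 2, shrink = 0.2,
                         steps_per_stage = 5) {
  stopifnot(inherits(config, "atomic_configuration"), is.function(calculator))
  if (!is_cubic(config)) stop_uq("border relaxation requires a cubic cell")
  if (fixed_core_factor <= 0 || fixed_core_factor >= 1)
    stop_uq("fixed_core_factor must be in (0, 1)")
  if (pad <= 0 || shrink <= 0) stop_uq("pad and shrink must be > 0")
  l_new <- config$cell[1, 1]
  n <- n_atoms(config)
  rel <- config$positions -
    matrix(config$positions[center, ], n, 3, byrow = TRUE)
  core <- which(sqrt(rowSums(rel^2)) <= fixed_core_factor * l_new / 2)
  free <- setdiff(seq_len(n), core)
  n_stages <- ceiling(pad / shrink - 1e-9)
  edges <- l_new + pad - shrink * (seq_len(n_stages) - 1)

  eval_at <- function(par, edge) {
    r <- rel
    if (length(free)) r[free, ] <- matrix(par, ncol = 3)
    cfg <- atomic_configuration(config$species, r + edge / 2,
                                cell = diag(3) * edge, pbc = TRUE)
    res <- calculator(cfg)
    if (!is.finite(res$energy) || !all(is.finite(res$forces)))
      stop_uq("calculator returned non-finite energy/forces")
    res
  }

  energy_log <- data.frame(stage = integer(0), edge = numeric(0),
                           energy = numeric(0))
  for (st in seq_len(n_stages)) {
    edge <- edges[st]
    if (length(free)) {
      # memoize the last evaluation: optim calls fn and gr at the same par
      memo <- new.env(parent = emptyenv())
      get_res <- function(par) {
        key <- paste(par, collapse = ",")
        if (!identical(memo$key, key)) {
          memo$res <- tryCatch(eval_at(par, edge), error = function(e)
            stop_uq("stage %d (edge %.3f A): %s", st, edge,
                    conditionMessage(e)))
          memo$key <- key
        }
        memo$res
      }
      opt <- optim(par = as.numeric(rel[free, ]),
                   fn = function(p) get_res(p)$energy,
                   gr = function(p) -as.numeric(get_res(p)$forces[free, ]),
                   method = "L-BFGS-B",
                   control = list(maxit = steps_per_stage))
      rel[free, ] <- matrix(opt$par, ncol = 3)
      e_now <- opt$value
    } else {
      e_now <- eval_at(numeric(0), edge)$energy
    }
    energy_log <- rbind(energy_log,
                        data.frame(stage = st, edge = edge, energy = e_now))
  }
  final <- atomic_configuration(config$species, rel + l_new / 2,
                                cell = diag(3) * l_new, pbc = TRUE)
  list(config = final, energy_log = energy_log, n_stages = n_stages,
       frozen = core)
}

#' One active-learning geometry round
#'
#' Composes [select_frames()], [extract_subbox()] and [relax_border()]:
#' picks one high-uncertainty (frame, center) pair per trajectory segment,
#' cuts a density-preserving subbox around each center, relaxes its
#' border, and returns structures ready for external ab initio labeling.
#' A failure in one pick is logged and does not abort the others.
#'
#' @inheritParams select_frames
#' @param calculator energy/forces callback for [relax_border()], or
#'   `NULL` to skip relaxation.
#' @param n_center_species,companions,companion_species,l_new passed to
#'   [extract_subbox()].
#' @param fixed_core_factor,pad,shrink,steps_per_stage passed to
#'   [relax_border()].
#' @return list with `structures` (relaxed subboxes), `plan` (the
#'   [select_frames()] report with a `status` column) and `failures`
#'   (messages, if any).
#' @export
al_round <- function(traj, n_segments = 10,
                     strategy = c("local_uncertainty", "atomic_uncertainty",
                                  "random"),
                     r_cut = 4, species = NULL, seed = NULL,
                     calculator = NULL,
                     n_center_species = 64, companions = 2,
                     companion_species = NULL, l_new = NULL,
                     fixed_core_factor = 0.8, pad = 2, shrink = 0.2,
                     steps_per_stage = 5) {
  plan <- select_frames(traj, n_segments, strategy, r_cut, species, seed)
  structures <- vector("list", nrow(plan))
  status <- character(nrow(plan))
  failures <- character(0)
  for (i in seq_len(nrow(plan))) {
    res <- tryCatch({
      sub <- extract_subbox(traj$configs[[plan$frame[i]]], plan$center[i],
                            n_center_species, companions,
                            companion_species, l_new)
      if (!is.null(calculator)) {
        rel <- relax_border(sub, attr(sub, "center_index"), calculator,
                            fixed_core_factor, pad, shrink,
                            steps_per_stage)$config
        attr(rel, "source_indices") <- attr(sub, "source_indices")
        attr(rel, "center_index") <- attr(sub, "center_index")
        attr(rel, "l_new") <- attr(sub, "l_new")
        sub <- rel
      }
      sub
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "failed"
      failures <- c(failures, sprintf("segment %d (frame %d, center %d): %s",
                                      plan$segment[i], plan$frame[i],
                                      plan$center[i], conditionMessage(res)))
    } else {
      status[i] <- "ok"
      structures[[i]] <- res
    }
  }
  plan$status <- status
  list(structures = structures[status == "ok"], plan = plan,
       failures = failures)
}
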