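test_that("per-atom scalars sum or average the three directions", {
  f <- per_component_field(rbind(c(0.1, 0.2, 0.3), c(0, 0, 0),
                                 c(0.3, 0.3, 0.3)), "uncertainty")
  expect_equal(per_atom_scalar(f), c(0.6, 0, 0.9))
  expect_equal(per_atom_scalar(f, "mean"), c(0.2, 0, 0.3))
})

test_that("the per-structure aggregate is the mean over all components", {
  expect_equal(structure_aggregate(matrix(c(1, 2, 3), 1, 3)), 2)
  expect_equal(structure_aggregate(matrix(0.7, 5, 3)), 0.7)
  expect_equal(structure_aggregate(rbind(c(0, 0, 0), c(3, 3, 3))), 1.5)
})

test_that("per-structure error aggregate equals an independent force MAE", {
  set.seed(21)
  pred <- matrix(rnorm(30), 10, 3)
  ref <- matrix(rnorm(30), 10, 3)
  e <- component_error(per_component_field(pred, "mean"), ref)
  expect_equal(structure_aggregate(e), mean(abs(pred - ref)))
})

test_that("neighbor shells handle isolation, wrapping, and self-inclusion", {
  iso <- atomic_configuration(c("X", "X"), rbind(c(0, 0, 0), c(10, 0, 0)))
  sh <- build_neighbor_shells(iso, 4)
  expect_equal(sh$neighbors, list(1L, 2L))
  expect_equal(sh$counts, c(1L, 1L))

  # atoms at fractional 0.05 and 0.95 of a 10 A periodic axis: 1 A apart
  wrap <- atomic_configuration(c("X", "X"), rbind(c(0.5, 5, 5), c(9.5, 5, 5)),
                               diag(3) * 10, TRUE)
  sh <- build_neighbor_shells(wrap, 1.5)
  expect_equal(sh$neighbors, list(c(1L, 2L), c(1L, 2L)))

  # r_cut = 0 still yields the self-shell (inclusive boundary)
  expect_equal(build_neighbor_shells(iso, 0)$counts, c(1L, 1L))
})

test_that("minimum-image shells match the brute-force replica oracle", {
  set.seed(22)
  for (rep in 1:12) {
    cfg <- random_periodic_config(sample(5:40, 1), triclinic = rep %% 2 == 0)
    r_cut <- runif(1, 1, 0.45 * min(forceuq:::cell_widths(cfg$cell)))
    sh <- build_neighbor_shells(cfg, r_cut)
    expect_identical(sh$neighbors, oracle_shells(cfg, r_cut))
    # symmetry of the metric
    for (j in seq_along(sh$neighbors))
      for (n in sh$neighbors[[j]])
        expect_true(j %in% sh$neighbors[[n]])
  }
})

test_that("oversized cutoffs warn and fall back to an exact replica search", {
  set.seed(23)
  cfg <- random_periodic_config(20)
  big <- 0.8 * min(forceuq:::cell_widths(cfg$cell))
  expect_warning(sh <- build_neighbor_shells(cfg, big), "replica search")
  expect_identical(sh$neighbors, oracle_shells(cfg, big))
})

test_that("local aggregation reproduces hand-computed collinear shells", {
  a <- 0.2; b <- 0.5; c <- 0.8
  cfg <- atomic_configuration(rep("X", 3),
                              cbind(c(0, 2, 4), 0, 0))
  f <- per_component_field(cbind(c(a, b, c), c(a, b, c), c(a, b, c)),
                           "uncertainty")
  loc <- local_aggregate(f, build_neighbor_shells(cfg, 2.5))
  expect_equal(loc, c((a + b) / 2, (a + b + c) / 3, (b + c) / 2))
})

test_that("local values converge exactly to the per-structure value", {
  set.seed(24)
  cfg <- random_periodic_config(30)
  f <- matrix(abs(rnorm(90)), 30, 3)
  big <- min(forceuq:::cell_widths(cfg$cell))   # >= any minimum-image distance
  sh <- suppressWarnings(build_neighbor_shells(cfg, big))
  expect_true(all(sh$counts == 30))
  expect_equal(local_aggregate(f, sh), rep(structure_aggregate(f), 30),
               tolerance = 1e-12)
})

test_that("local aggregation is permutation-equivariant and kernel-free", {
  set.seed(25)
  cfg <- random_periodic_config(25)
  f <- matrix(abs(rnorm(75)), 25, 3)
  loc <- local_aggregate(f, build_neighbor_shells(cfg, 3))
  p <- sample(25)
  cfg_p <- atomic_configuration(cfg$species[p], cfg$positions[p, ],
                                cfg$cell, cfg$pbc)
  expect_equal(local_aggregate(f[p, ], build_neighbor_shells(cfg_p, 3)),
               loc[p])
  # uniform fields are fixed points of every aggregation level
  u <- matrix(0.4, 25, 3)
  expect_equal(local_aggregate(u, build_neighbor_shells(cfg, 3)),
               rep(0.4, 25))
})

test_that("the maximum local uncertainty is an argmax with stable ties", {
  expect_equal(max_local_uncertainty(c(0.1, 0.5, 0.2)),
               list(atom = 2L, value = 0.5))
  expect_equal(max_local_uncertainty(rep(0.3, 5))$atom, 1L)
  set.seed(26)
  v <- runif(50)
  got <- max_local_uncertainty(v)
  expect_equal(got$atom, which(v == max(v))[1])
  expect_equal(got$value, max(v))
})

test_that("uncertainty_field assembles all aggregation levels", {
  set.seed(27)
  cfg <- random_periodic_config(20)
  s <- per_component_field(matrix(abs(rnorm(60)), 20, 3), "uncertainty")
  uf <- uncertainty_field(s, cfg, r_cut = 3)
  expect_equal(uf$per_structure, mean(s))
  expect_equal(uf$per_atom, rowSums(s))
  expect_equal(uf$local,
               local_aggregate(s, build_neighbor_shells(cfg, 3)))
  tab <- field_table(uf, "s1")
  expect_equal(nrow(tab), 20)
  expect_equal(tab$local, uf$local)
})
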