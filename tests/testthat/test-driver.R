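test_that("clone seeding places paired, uniformly spread lineages", {
  set.seed(101)
  tt <- build_initial_grid(220)
  t2 <- seed_clones(tt, 20L)
  expect_equal(sum(t2$genotype == 1L), 20L)
  expect_equal(sum(t2$genotype == 2L), 20L)
  expect_equal(sum(t2$genotype == 0L), 180L)
  expect_equal(sort(unique(t2$clone_id[!is.na(t2$clone_id)])), 1:20)
  ## every mutant has its twin as a neighbor
  adj <- wingvertex:::cell_adjacency(t2)
  for (m in which(t2$genotype == 1L)) {
    tw <- which(t2$genotype == 2L & t2$clone_id == t2$clone_id[m])
    expect_true(tw %in% adj[[m]])
  }
  ## labels are only ever background / one mutant + one twin per id
  expect_true(all(table(t2$clone_id[!is.na(t2$clone_id)]) == 2L))
  ## n = 0 leaves the tissue unchanged
  expect_identical(seed_clones(tt, 0L), tt)
  ## over-packing is refused
  expect_error(seed_clones(hex_strip(2, 3), 3L))
})

test_that("a cycle without division leaves the topology unchanged", {
  set.seed(55)
  cfg <- sim_config(seed = 55, n_start = 24L, n_stop = 30L,
                    signaling_tmax = 200)
  tt <- build_initial_grid(24L)
  tt <- advance_signaling(tt, cfg$kinetics, tol = cfg$signaling_tol,
                          t_max = 3000, on_fail = "warn")
  tt <- relax(tt, cfg$mech, compute_factors(tt), tol = cfg$relax_tol,
              on_fail = "warn")
  t2 <- suppressWarnings(growth_cycle(tt, cfg))
  expect_false(attr(t2, "divided"))
  expect_identical(lengths(t2$cells), lengths(tt$cells))
  expect_equal(n_cells(t2), n_cells(tt))
  ## exactly one cell is growing now
  expect_equal(sum(t2$target_area > 1), 1L)
})

test_that("genotype and compartment labels are conserved through growth", {
  set.seed(66)
  cfg <- sim_config(seed = 66, n_start = 63L, n_stop = 75L, clones = TRUE,
                    n_mutant = 4L, signaling_tmax = 300,
                    snapshot_every = 1000L)
  run <- suppressWarnings(simulate_disc(cfg))
  tt <- run$tissue
  expect_equal(n_cells(tt), 75L)
  ## no relabeling ever happens: mutant and twin lineages persist (up to
  ## the rare extrusion of a fully crushed cell) and clone ids still pair
  ## with their genotypes
  expect_gte(sum(tt$genotype == 1L), 3L)
  expect_gte(sum(tt$genotype == 2L), 3L)
  expect_true(all(tt$genotype[is.na(tt$clone_id)] == 0L))
  expect_true(all(tt$genotype[!is.na(tt$clone_id)] != 0L))
  audit_tissue(tt)
})

test_that("identical seeds give bit-identical runs; n_stop = n_start relaxes only", {
  cfg <- sim_config(seed = 7L, n_start = 24L, n_stop = 32L,
                    signaling_tmax = 200)
  r1 <- suppressWarnings(simulate_disc(cfg))
  r2 <- suppressWarnings(simulate_disc(cfg))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$tissue$xy, r2$tissue$xy)

  cfg0 <- sim_config(seed = 7L, n_start = 24L, n_stop = 24L,
                     signaling_tmax = 200)
  r0 <- suppressWarnings(simulate_disc(cfg0))
  expect_equal(n_cells(r0$tissue), 24L)
  expect_equal(max(r0$metrics$divisions), 0L)
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(n_start = 100L, n_stop = 50L))
  expect_error(sim_config(clones = TRUE, n_start = 40L, n_mutant = 20L),
               "quarter")
  expect_error(sim_config(relax_tol = 0))
})
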