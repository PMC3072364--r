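test_that("analytic gradient matches finite differences on random meshes", {
  set.seed(11)
  params <- mech_params()
  for (rep in 1:3) {
    tt <- hex_strip(2 + rep %% 2, 3)
    tt$xy <- tt$xy + matrix(rnorm(length(tt$xy), 0, 0.03), ncol = 2)
    tt$conc[, "TMx"] <- runif(n_cells(tt), 0.2, 2.4)
    f <- compute_factors(tt)
    ga <- energy_gradient(tt, params, f)
    gn <- fd_gradient(tt, params, f)
    expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-5)
  }
})

test_that("unit factors reproduce the base model energy", {
  tt <- hex_strip(3, 3)
  params <- mech_params()
  e0 <- tissue_energy(tt, params, NULL)
  e1 <- tissue_energy(tt, params, unit_factors(tt))
  expect_equal(e1$total, e0$total, tolerance = 1e-14)
  expect_equal(e1$tension + e1$area + e1$perimeter, e1$total,
               tolerance = 1e-12)
})

test_that("energy is invariant under rigid motions", {
  tt <- hex_strip(2, 3)
  tt$conc[, "TMx"] <- seq(0.2, 1, length.out = n_cells(tt))
  f <- compute_factors(tt)
  params <- mech_params()
  e0 <- tissue_energy(tt, params, f)$total
  ## translation
  t2 <- tt
  t2$xy <- tt$xy + matrix(c(1.3, -0.7), nrow(tt$xy), 2, byrow = TRUE)
  expect_equal(tissue_energy(t2, params, compute_factors(t2))$total, e0,
               tolerance = 1e-12)
  ## rotation
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t3 <- tt
  t3$xy <- tt$xy %*% R
  expect_equal(tissue_energy(t3, params, compute_factors(t3))$total, e0,
               tolerance = 1e-12)
})

test_that("a lone unit-area hexagon with zero coefficients has zero energy", {
  tt <- build_initial_grid(1)
  e <- tissue_energy(tt, mech_params(lambda_bar = 0, gamma_bar = 0,
                                     lambda_bar_margin = 0))
  expect_equal(e$total, 0, tolerance = 1e-12)
})

test_that("missing or stale tension factors are an error", {
  tt <- hex_strip(2, 2)
  tt$conc[, "TMx"] <- 0.2
  f <- compute_factors(tt)
  t2 <- divide_cell(tt, 1L, pi / 2)
  expect_error(tissue_energy(t2, mech_params(), f), "recompute")
})

test_that("the interior of a perfect hexagonal lattice is a fixed point", {
  tt <- hex_strip(5, 5)
  g <- energy_gradient(tt, mech_params())
  ed <- tissue_edges(tt)
  marg_v <- unique(c(ed$v1[ed$margin], ed$v2[ed$margin]))
  interior <- setdiff(seq_len(nrow(tt$xy)), marg_v)
  ## force balance by symmetry on every interior threefold vertex
  expect_lt(max(abs(g[interior, ])), 1e-12)
  ## and relaxation after perturbing the interior restores it exactly
  set.seed(5)
  t2 <- tt
  t2$xy[interior, ] <- tt$xy[interior, ] +
    matrix(rnorm(2 * length(interior), 0, 0.01), ncol = 2)
  free <- logical(nrow(tt$xy))
  free[interior] <- TRUE
  t3 <- relax(t2, mech_params(), tol = 1e-8, t1 = FALSE,
              free_vertices = free)
  expect_lt(max(abs(t3$xy[interior, ] - tt$xy[interior, ])), 1e-4)
})

test_that("relaxation never increases the energy", {
  set.seed(9)
  tt <- hex_strip(4, 4)
  tt$xy <- tt$xy + matrix(rnorm(length(tt$xy), 0, 0.05), ncol = 2)
  tt$conc[, "TMx"] <- runif(n_cells(tt), 0.2, 2.4)
  f <- compute_factors(tt)
  e0 <- tissue_energy(tt, mech_params(), f)$total
  t2 <- relax(tt, mech_params(), f, tol = 1e-6, t1 = FALSE)
  e1 <- attr(t2, "relax_info")$energy
  expect_lt(e1, e0)
  expect_true(attr(t2, "relax_info")$converged)
})

test_that("edges shorten under increased factors and lengthen under decreased", {
  ## two-cell fixture with a TMx imbalance: the shared edge takes the max
  ## bond value for both cells, so the high-TMx cell's other edges drop
  ## below 1 and the shared edge's effective factor rises above 1
  tt <- two_cell_fixture()
  tt$conc[, "TMx"] <- c(1, 5)
  f <- compute_factors(tt)
  ed <- tissue_edges(tt)
  shared <- which(!ed$margin)
  expect_gt(f$lambda_bar[shared], 1)
  len0 <- function(t, k) {
    sqrt(sum((t$xy[ed$v2[k], ] - t$xy[ed$v1[k], ])^2))
  }
  t_hi <- relax(tt, mech_params(), f, tol = 1e-7, t1 = FALSE)
  t_un <- relax(tt, mech_params(), NULL, tol = 1e-7, t1 = FALSE)
  expect_lt(len0(t_hi, shared), len0(t_un, shared))
  ## the low-TMx cell's own edges carry factors < 1 and lengthen
  low <- which(ed$margin & ed$c1 == 1L & f$lambda_bar < 1)[1L]
  expect_gt(len0(t_hi, low), len0(t_un, low))
})

test_that("tension proxy reports effective tension ratios", {
  tt <- hex_strip(6, 8)
  params <- mech_params()
  f1 <- unit_factors(tt)
  ed <- tissue_edges(tt)
  internal <- which(!ed$margin)
  vals <- vapply(internal[1:10], function(k) {
    laser_ablation_proxy(tt, params, f1, k)
  }, numeric(1))
  expect_true(all(abs(vals / vals[1L] - 1) < 1e-12))
  expect_error(laser_ablation_proxy(tt, params, f1, which(ed$margin)[1L]),
               "internal")

  ## calibrated boundary step: boundary-vs-bulk proxy ratio roughly two
  t2 <- tmx_step_profile(tt)
  f2 <- compute_factors(t2)
  comp <- t2$compartment
  bnd <- which(!ed$margin & comp[ed$c1] != comp[ed$c2])
  blk <- which(!ed$margin & comp[ed$c1] == comp[ed$c2] &
                 abs(f2$lambda_bar - 1) < 1e-9)
  r <- mean(vapply(bnd, function(k) laser_ablation_proxy(t2, params, f2, k),
                   numeric(1))) /
    mean(vapply(blk, function(k) laser_ablation_proxy(t2, params, f2, k),
                numeric(1)))
  expect_gt(r, 1.4)
  expect_lt(r, 2.6)
  ## scale invariance of the ratio
  t3 <- t2
  t3$conc[, "TMx"] <- 7.3 * t2$conc[, "TMx"]
  f3 <- compute_factors(t3)
  expect_equal(f3$lambda_bar, f2$lambda_bar, tolerance = 1e-12)
})
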