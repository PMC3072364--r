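test_that("diffusion leaves a uniform field unchanged and conserves mass", {
  tt <- hex_strip(4, 4)
  tt$conc[, "Hh"] <- 0.8
  t2 <- diffusion_step(tt, D = 1.6, dt = 0.05)
  expect_equal(t2$conc[, "Hh"], tt$conc[, "Hh"], tolerance = 1e-14)

  set.seed(13)
  tt$conc[, "Hh"] <- runif(n_cells(tt), 0, 3)
  total0 <- sum(tt$conc[, "Hh"] * cell_areas(tt))
  t3 <- tt
  for (i in 1:50) t3 <- diffusion_step(t3, D = 1.6, dt = 0.05)
  expect_equal(sum(t3$conc[, "Hh"] * cell_areas(t3)), total0,
               tolerance = 1e-12)
  ## other species untouched
  expect_identical(t3$conc[, -1L], tt$conc[, -1L])
})

test_that("the stability bound is enforced by name", {
  tt <- hex_strip(3, 3)
  expect_error(diffusion_step(tt, D = 1.6, dt = 10), "stability bound")
})

test_that("a sourced, decaying chain matches the tridiagonal linear solve", {
  ## 1 x 12 chain; Hh produced in the single posterior end cell, uniform
  ## decay, diffusion only (all other reactions off)
  n <- 12L
  tt <- hex_strip(1, n)
  tt$compartment <- c(rep(1L, n - 1L), 2L)
  p <- kinetic_params(rho_Hh_P = 0.3, delta_Hh = 0.2,
                      k_on = 0, k_off = 0, rho_Ptc_basal_A = 0,
                      k_Ptc_Smo_A = 0, rho_Smo = 0, rho_Lx = 0, k_pump = 0,
                      k_f = 0, k_r = 0, rho_TMx_basal = 0, k_TMx_Smo_A = 0,
                      delta_Ptc = 0, delta_HhPtc = 0, delta_Smo = 0,
                      delta_Lx = 0, delta_LxSmo = 0, delta_TMx = 0)
  out <- advance_signaling(tt, p, tol = 1e-10, t_max = 20000,
                           dt_macro = 0.02)
  ## oracle: steady state of  D L h - delta A h + b = 0  solved directly
  fw <- wingvertex:::fv_weights(tt)
  areas <- cell_areas(tt)
  M <- matrix(0, n, n)
  for (k in seq_along(fw$w)) {
    i <- fw$c1[k]; j <- fw$c2[k]
    w <- p[["D"]] * fw$w[k]
    M[i, i] <- M[i, i] - w; M[i, j] <- M[i, j] + w
    M[j, j] <- M[j, j] - w; M[j, i] <- M[j, i] + w
  }
  M <- M - diag(p[["delta_Hh"]] * areas)
  b <- rep(0, n); b[n] <- -p[["rho_Hh_P"]] * areas[n]
  h_exact <- solve(M, b)
  expect_equal(out$conc[, "Hh"], h_exact, tolerance = 1e-5)
})

test_that("kinetics closed forms: smo mutants, twins and posterior basal", {
  p <- kinetic_params()
  ## smo-mutant cell: Smo and LxSmo decay to zero, TMx settles at basal
  st <- setNames(c(0, 0, 0, 1, 0.5, 0.5, 1), wingvertex:::SPECIES)
  lab <- list(compartment = "anterior", genotype = "smo_mutant")
  for (i in 1:4000) st <- kinetics_step(st, lab, p, 0.05)
  expect_lt(st[["Smo"]], 1e-6)
  expect_lt(st[["LxSmo"]], 1e-6)
  expect_equal(st[["TMx"]], p[["rho_TMx_basal"]] / p[["delta_TMx"]],
               tolerance = 1e-4)

  ## isolated posterior cell from an all-zero start: TMx -> basal exactly
  ## (the induction term is anterior-only)
  st0 <- setNames(rep(0, 7), wingvertex:::SPECIES)
  lab_p <- list(compartment = "posterior", genotype = "background")
  st1 <- st0
  for (i in 1:4000) st1 <- kinetics_step(st1, lab_p, p, 0.05)
  expect_equal(st1[["TMx"]], p[["rho_TMx_basal"]] / p[["delta_TMx"]],
               tolerance = 1e-4)

  ## a twin-spot cell integrates exactly doubled Smo production: with the
  ## binding partners silenced its Smo level is twice background
  p2 <- kinetic_params(k_f = 0, k_pump = 0)
  lab_bg <- list(compartment = "posterior", genotype = "background")
  lab_tw <- list(compartment = "posterior", genotype = "twin_spot")
  s_bg <- st0; s_tw <- st0
  for (i in 1:3000) {
    s_bg <- kinetics_step(s_bg, lab_bg, p2, 0.05)
    s_tw <- kinetics_step(s_tw, lab_tw, p2, 0.05)
  }
  expect_equal(s_tw[["Smo"]], 2 * s_bg[["Smo"]], tolerance = 1e-8)
})

test_that("operator-split integration matches a monolithic solve within 1%", {
  tt <- two_cell_fixture()
  p <- kinetic_params()
  split <- advance_signaling(tt, p, tol = 1e-9, t_max = 30000)
  mono <- monolithic_steady(tt, p)
  rel <- abs(split$conc - mono) / pmax(abs(mono), 0.01)
  expect_lt(max(rel), 0.01)
})

test_that("the steady state does not depend on the initial condition", {
  tt <- hex_strip(3, 6)
  p <- kinetic_params()
  s1 <- advance_signaling(tt, p, tol = 1e-8, t_max = 30000)
  t2 <- tt
  set.seed(3)
  t2$conc[] <- runif(length(t2$conc), 0, 2)
  s2 <- advance_signaling(t2, p, tol = 1e-8, t_max = 30000)
  expect_equal(s2$conc, s1$conc, tolerance = 1e-4)
})

test_that("concentrations stay non-negative along the integration", {
  tt <- hex_strip(2, 4)
  set.seed(8)
  tt$conc[] <- runif(length(tt$conc), 0, 0.1)
  out <- advance_signaling(tt, kinetic_params(), tol = 1e-6, t_max = 5000)
  expect_true(all(out$conc >= 0))
})

test_that("the calibrated steady profile has the documented shape", {
  pr <- cached_runs("profile20", function() {
    steady_profile(hex_strip(20, 20), kinetic_params(), tol = 1e-5)
  })
  cells <- pr$cells
  ant <- cells$compartment == "anterior"
  ## total Ptc: monotone non-increasing with distance into the anterior
  ## compartment, maximal in the first row (sigmoid stripe)
  ptc_rows <- tapply(cells$Ptc_T[ant], cells$row[ant], mean)
  expect_true(all(diff(ptc_rows) < 0))
  expect_equal(which.max(ptc_rows), 1L, ignore_attr = TRUE)
  ## graded anterior TMx stripe at least 10 rows wide
  tmx_rows <- tapply(cells$TMx[ant], cells$row[ant], mean)
  basal <- mean(cells$TMx[!ant])
  expect_true(all(diff(tmx_rows) < 0))
  expect_gte(sum(tmx_rows > 1.1 * basal), 10L)
  ## twelve-fold A1 contrast
  expect_equal(tmx_rows[[1L]] / basal, 12, tolerance = 0.2)
  expect_equal(tmx_rows[[1L]], 2.4, tolerance = 0.2)
  expect_equal(basal, 0.2, tolerance = 0.02)
})

test_that("without diffusion, Hh stays posterior and anterior TMx is flat", {
  tt <- hex_strip(6, 6)
  p <- kinetic_params(D = 1e-12)
  out <- advance_signaling(tt, p, tol = 1e-7, t_max = 20000)
  ant <- out$compartment == 1L
  expect_lt(max(out$conc[ant, "Hh"]), 1e-4)
  ## no Hh input: the anterior TMx field is spatially uniform (a small
  ## pump-leak offset above basal, far below the induced A1 level) so no
  ## graded stripe and no tension patterning exist
  tmx <- out$conc[ant, "TMx"]
  expect_lt(diff(range(tmx)) / mean(tmx), 1e-3)
  expect_lt(max(tmx), 0.5)
  f <- compute_factors(out)
  comp <- out$compartment
  bulk_a <- !f$margin & comp[f$c1] == 1L &
    !is.na(f$c2) & comp[f$c2] == 1L
  expect_equal(f$lambda_bar[bulk_a], rep(1, sum(bulk_a)), tolerance = 1e-6)
})
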