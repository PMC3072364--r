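test_that("uniform TMx yields factors of exactly one everywhere", {
  for (tt in list(hex_strip(3, 3), hex_strip(1, 5), build_initial_grid(20))) {
    tt$conc[, "TMx"] <- 0.7
    f <- compute_factors(tt)
    expect_equal(f$lambda_bar, rep(1, nrow(f)))
    expect_equal(f$lambda1, rep(1, nrow(f)))
  }
})

test_that("factors are invariant under global TMx rescaling", {
  set.seed(21)
  tt <- hex_strip(4, 4)
  tmx <- runif(n_cells(tt), 0.2, 2.4)
  f1 <- compute_factors(tt, tmx)
  f2 <- compute_factors(tt, 7.3 * tmx)
  expect_equal(f2$lambda_bar, f1$lambda_bar, tolerance = 1e-14)
  expect_equal(f2$lambda1, f1$lambda1, tolerance = 1e-14)
})

test_that("the hexagon worked example gives 72/17 and 6/17", {
  fx <- flower_fixture()
  tt <- fx$tissue
  tmx <- rep(1, n_cells(tt))
  ## one neighbor of the central cell at twelve-fold concentration
  adj <- wingvertex:::cell_adjacency(tt)
  hot <- adj[[fx$center]][1L]
  tmx[hot] <- 12
  f <- compute_factors(tt, tmx)
  ## central cell: bond values (12, 1, 1, 1, 1, 1), mean 17/6
  ctr_rows <- which(f$c1 == fx$center | f$c2 == fx$center)
  lam_ctr <- ifelse(f$c1[ctr_rows] == fx$center,
                    f$lambda1[ctr_rows], f$lambda2[ctr_rows])
  hot_edge <- ctr_rows[(f$c1[ctr_rows] == hot) | (!is.na(f$c2[ctr_rows]) &
                                                    f$c2[ctr_rows] == hot)]
  lam_hot <- ifelse(f$c1[hot_edge] == fx$center,
                    f$lambda1[hot_edge], f$lambda2[hot_edge])
  expect_equal(lam_hot, 72 / 17, tolerance = 1e-12)
  expect_equal(sort(unique(round(lam_ctr, 12))),
               round(c(6 / 17, 72 / 17), 12))
  expect_equal(mean(lam_ctr), 1, tolerance = 1e-12)
})

test_that("per-cell factor means are one after every recomputation", {
  set.seed(31)
  tt <- hex_strip(5, 5)
  for (rep in 1:5) {
    tmx <- runif(n_cells(tt), 0.1, 3)
    f <- compute_factors(tt, tmx)
    inc_cell <- c(f$c1, f$c2[!is.na(f$c2)])
    lam <- c(f$lambda1, f$lambda2[!is.na(f$c2)])
    means <- tapply(lam, inc_cell, mean)
    expect_lt(max(abs(means - 1)), 1e-12)
    expect_true(all(f$lambda_bar > 0))
  }
})

test_that("raising one cell's TMx never lowers its edge factors", {
  fx <- flower_fixture()
  tt <- fx$tissue
  base <- rep(1, n_cells(tt))
  prev <- NULL
  for (mult in c(1, 2, 4, 8, 12)) {
    tmx <- base
    tmx[fx$center] <- mult
    f <- compute_factors(tt, tmx)
    rows <- which(f$c1 == fx$center | (!is.na(f$c2) & f$c2 == fx$center))
    cur <- sort(f$lambda_bar[rows])
    if (!is.null(prev)) {
      ## effective factors on the raised cell's edges with lower-TMx
      ## neighbors are non-decreasing in the imbalance
      expect_true(all(max(cur) >= max(prev) - 1e-12))
    }
    prev <- cur
  }
})

test_that("non-positive TMx is rejected", {
  tt <- hex_strip(2, 2)
  expect_error(compute_factors(tt, c(1, 1, 0, 1)), "positive")
  expect_error(compute_factors(tt, rep(-1, 4)), "positive")
  expect_error(compute_factors(tt, rep(1, 3)), "per cell")
})

test_that("boundary tension ratio responds to the TMx step", {
  tt <- hex_strip(12, 14)
  tt$conc[, "TMx"] <- 0.2
  expect_equal(boundary_tension_ratio(tt, compute_factors(tt)), 1,
               tolerance = 1e-12)
  ## ratio grows monotonically with the imposed A1/basal contrast
  ratios <- vapply(c(1, 2, 4, 6, 12), function(r) {
    t2 <- tmx_step_profile(tt, basal = 0.2, a1 = 0.2 * r)
    boundary_tension_ratio(t2, compute_factors(t2))
  }, numeric(1))
  expect_true(all(diff(ratios) > -1e-12))
  expect_equal(ratios[1L], 1, tolerance = 1e-12)
  expect_gt(ratios[5L], 1.4)
  expect_lt(ratios[5L], 2.6)
})

test_that("length-weighted normalization variant also averages to one", {
  set.seed(12)
  tt <- hex_strip(3, 3)
  tt$xy <- tt$xy + matrix(rnorm(length(tt$xy), 0, 0.05), ncol = 2)
  tmx <- runif(n_cells(tt), 0.2, 2.4)
  f <- compute_factors(tt, tmx, length_weighted = TRUE)
  expect_true(all(f$lambda_bar > 0))
  ## weighted mean of per-cell factors equals one under the same weights
  ed <- f
  len <- sqrt((tt$xy[ed$v2, 1L] - tt$xy[ed$v1, 1L])^2 +
                (tt$xy[ed$v2, 2L] - tt$xy[ed$v1, 2L])^2)
  for (cell in seq_len(n_cells(tt))) {
    rows <- which(ed$c1 == cell | (!is.na(ed$c2) & ed$c2 == cell))
    lam <- ifelse(ed$c1[rows] == cell, ed$lambda1[rows], ed$lambda2[rows])
    expect_equal(sum(lam * len[rows]) / sum(len[rows]), 1, tolerance = 1e-12)
  }
})
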