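test_that("roundness matches closed forms and is invariant to rigid motions", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(roundness(sq), pi / 4, tolerance = 1e-12)

  hexp <- t(vapply(0:5, function(k) cos(k * pi / 3 + c(0, -pi / 2)) *
                     c(1, -1), numeric(2)))
  hexp <- cbind(cos(0:5 * pi / 3), sin(0:5 * pi / 3))
  expect_equal(roundness(hexp), pi * sqrt(3) / 6, tolerance = 1e-12)

  ## fine polygonal circle approaches the isoperimetric bound
  th <- seq(0, 2 * pi, length.out = 257L)[-257L]
  circ <- cbind(cos(th), sin(th))
  expect_gt(roundness(circ), 0.999)
  expect_lte(roundness(circ), 1)

  ## rigid motion + uniform scaling
  thr <- 0.4
  R <- matrix(c(cos(thr), sin(thr), -sin(thr), cos(thr)), 2)
  moved <- 3.7 * sq %*% R + matrix(c(5, -1), 4, 2, byrow = TRUE)
  expect_equal(roundness(moved), roundness(sq), tolerance = 1e-12)

  expect_error(roundness(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("clone outlines are the union boundary of member cells", {
  tt <- hex_strip(1, 2)
  tt$clone_id <- c(1L, 1L)
  out <- clone_outline(tt, 1L)
  ## two fused hexagons: 10 outline vertices, shared edge interior
  expect_equal(nrow(out), 10L)
  expect_equal(wingvertex:::poly_area(out), sum(cell_areas(tt)),
               tolerance = 1e-12)

  ## single cell: its own hexagon
  t1 <- hex_strip(2, 2)
  t1$clone_id[3L] <- 7L
  o1 <- clone_outline(t1, 7L)
  expect_equal(nrow(o1), 6L)
  expect_equal(abs(wingvertex:::poly_area(o1)), cell_areas(t1)[3L],
               tolerance = 1e-12)

  ## disconnected clones are refused with the component sizes
  t2 <- hex_strip(1, 5)
  t2$clone_id[c(1L, 5L)] <- 2L
  expect_error(clone_outline(t2, 2L), "disconnected")
})

test_that("boundary distance is signed, calibrated and symmetric", {
  tt <- hex_strip(9, 12)
  ctr <- cell_centroids(tt)
  rows <- wingvertex:::rows_from_boundary(tt)
  ## a clone centered n rows into the anterior sits n-ish cell diameters
  ## from the interface; at 2 um per diameter the sign is positive
  a5 <- which(tt$compartment == 1L & rows == 5L)
  mid <- a5[which.min(abs(ctr[a5, 2L] - median(ctr[a5, 2L])))]
  tt$clone_id[mid] <- 1L
  d_a <- boundary_distance(tt, 1L, um_per_cell_diameter = 2)
  expect_gt(d_a, 0)
  ## row 5 center is 4.5 column widths = 4.5 * 1.5R from the zigzag
  ## interface; compare against the direct construction
  R <- wingvertex:::hex_edge_unit_area()
  expected_um <- (4.5 * 1.5 * R) / sqrt(2 / sqrt(3)) * 2
  expect_equal(d_a, expected_um, tolerance = 0.05)

  ## mirror clone in the posterior flips the sign
  p5 <- which(tt$compartment == 2L & rows == 5L)
  midp <- p5[which.min(abs(ctr[p5, 2L] - median(ctr[p5, 2L])))]
  t2 <- tt
  t2$clone_id[] <- NA_integer_
  t2$clone_id[midp] <- 1L
  d_p <- boundary_distance(t2, 1L, um_per_cell_diameter = 2)
  expect_lt(d_p, 0)
  expect_equal(abs(d_p), abs(d_a), tolerance = 0.1)

  ## a clone straddling the interface has near-zero distance
  t3 <- tt
  t3$clone_id[] <- NA_integer_
  b1 <- which(rows == 1L)
  byy <- b1[order(abs(ctr[b1, 2L] - median(ctr[b1, 2L])))][1:2]
  t3$clone_id[byy] <- 1L
  expect_lt(abs(boundary_distance(t3, 1L)), 2)
})

test_that("trend analysis recovers planted slopes and controls type I error", {
  set.seed(77)
  mk_records <- function(n, slope) {
    d <- runif(n, 5, 30)
    data.frame(
      clone_id = seq_len(n), genotype = "smo_mutant",
      compartment = "anterior", n_cells = 5L, area = 1, perimeter = 4,
      roundness = 0.6 + slope * d + rnorm(n, 0, 0.05),
      distance_um = d
    )
  }
  tr <- roundness_trend(mk_records(80, -0.01))
  g <- tr[["smo_mutant.anterior"]]
  expect_lt(g$p_value, 0.01)
  expect_lt(g$slope, 0)
  expect_equal(g$slope, -0.01, tolerance = 0.5)
  expect_true(all(diff(g$moving_average$distance) > 0))

  ## type-I error of the slope test at the nominal 5% level
  reps <- 400L
  hits <- 0L
  for (r in seq_len(reps)) {
    tr0 <- roundness_trend(mk_records(40, 0))
    if (tr0[["smo_mutant.anterior"]]$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)

  ## permuting the (roundness, distance) pairing destroys a real trend
  rec <- mk_records(120, -0.012)
  rec$roundness <- sample(rec$roundness)
  trp <- roundness_trend(rec)
  expect_gt(trp[["smo_mutant.anterior"]]$p_value, 0.001)

  ## the distance filter and the minimum group size are enforced
  few <- mk_records(10, 0)
  few$distance_um <- runif(10, 0, 4.9)
  expect_error(roundness_trend(few), "fewer than 3")
})

test_that("polygon statistics on a perfect lattice are all hexagons", {
  st <- polygon_stats(hex_strip(10, 10))
  expect_equal(names(which.max(st$class_freq)), "6")
  expect_equal(unname(st$class_freq[["6"]]), 1)
  expect_equal(unname(st$class_area[["6"]]), 1, tolerance = 1e-12)
  expect_true(all(c("A1", "P1") %in% st$rows$row))
})

test_that("boundary roughness is one for a straight interface", {
  sq <- square_fixture()
  expect_equal(boundary_roughness(sq), 1, tolerance = 1e-12)
  ## hexagonal lattices cannot do better than the slant-edge zigzag
  expect_equal(boundary_roughness(hex_strip(8, 8)), 2 / sqrt(3),
               tolerance = 0.01)
  t2 <- hex_strip(2, 2)
  t2$compartment <- rep(1L, 4L)
  expect_error(boundary_roughness(t2), "boundary")
})
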