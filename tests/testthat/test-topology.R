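test_that("a vertical division of a regular hexagon gives equal pentagons", {
  tt <- build_initial_grid(1)
  tt$compartment <- 1L
  t2 <- divide_cell(tt, 1L, pi / 2)
  d <- attr(t2, "daughters")
  expect_length(d, 2L)
  a <- cell_areas(t2)
  expect_equal(a[d[1L]], a[d[2L]], tolerance = 1e-12)
  expect_equal(lengths(t2$cells[d]), c(5L, 5L))
  audit_tissue(t2)
})

test_that("daughters inherit the mother's labels for any angle", {
  set.seed(41)
  tt <- hex_strip(3, 4)
  tt$genotype[5L] <- 1L
  tt$clone_id[5L] <- 3L
  for (rep in 1:10) {
    cell <- sample.int(n_cells(tt), 1L)
    t2 <- tryCatch(divide_cell(tt, cell, runif(1, 0, pi)),
                   wingvertex_retry = function(e) NULL)
    if (is.null(t2)) next
    d <- attr(t2, "daughters")
    expect_equal(t2$compartment[d[1L]], t2$compartment[d[2L]])
    expect_equal(t2$genotype[d[1L]], t2$genotype[d[2L]])
    expect_equal(t2$clone_id[d[1L]], t2$clone_id[d[2L]])
    audit_tissue(t2)
    tt <- t2
  }
})

test_that("division conserves total molecule amounts to machine precision", {
  set.seed(7)
  tt <- hex_strip(3, 3)
  tt$conc[] <- runif(length(tt$conc), 0.1, 2)
  tot0 <- colSums(tt$conc * cell_areas(tt))
  for (rep in 1:6) {
    cell <- sample.int(n_cells(tt), 1L)
    t2 <- tryCatch(divide_cell(tt, cell, runif(1, 0, pi)),
                   wingvertex_retry = function(e) NULL)
    if (!is.null(t2)) tt <- t2
  }
  tot1 <- colSums(tt$conc * cell_areas(tt))
  expect_equal(tot1, tot0, tolerance = 1e-12)
})

test_that("inadmissible division lines trigger the retry contract", {
  tt <- build_initial_grid(1)
  ## the horizontal axis passes through two vertices of a flat-top hexagon
  expect_error(divide_cell(tt, 1L, 0), class = "wingvertex_retry")
})

test_that("T1 swaps adjacency and edge counts change by one", {
  tq <- hex_strip(3, 3)
  ed <- tissue_edges(tq)
  pair_adj <- function(e, a, b) {
    any((e$c1 == a & e$c2 == b) | (e$c1 == b & e$c2 == a), na.rm = TRUE)
  }
  ## a fully interior junction: both endpoints shared by three cells
  n_at <- function(v) sum(vapply(tq$cells, function(cyc) any(cyc == v),
                                 logical(1)))
  k <- which(!ed$margin &
               vapply(ed$v1, n_at, numeric(1)) == 3L &
               vapply(ed$v2, n_at, numeric(1)) == 3L)[1L]
  c1 <- ed$c1[k]; c2 <- ed$c2[k]
  n_before <- lengths(tq$cells)
  tt <- t1_transition(tq, ed$v1[k], ed$v2[k], 0.2)
  expect_true(attr(tt, "did_t1"))
  audit_tissue(tt)
  ed2 <- tissue_edges(tt)
  expect_false(pair_adj(ed2, c1, c2))
  ## exactly four cells are involved: the sharing pair loses one edge
  ## each, the two formerly non-adjacent cells gain one each
  delta <- lengths(tt$cells) - n_before
  expect_equal(sum(delta == 1L), 2L)
  expect_equal(sum(delta == -1L), 2L)
  expect_equal(sum(delta != 0L), 4L)

  ## applying the exchange again restores the original adjacency
  tt2 <- t1_transition(tt, ed$v1[k], ed$v2[k], 0.2)
  expect_true(attr(tt2, "did_t1"))
  audit_tissue(tt2)
  expect_true(pair_adj(tissue_edges(tt2), c1, c2))
})

test_that("forbidden T1s are refused with a warning and leave the mesh intact", {
  tq <- hex_strip(2, 2)
  ed <- tissue_edges(tq)
  k <- which(ed$margin)[1L]
  expect_warning(tt <- t1_transition(tq, ed$v1[k], ed$v2[k], 0.2),
                 "not internal")
  expect_false(attr(tt, "did_t1"))
  expect_identical(tt$cells, tq$cells)

  ## squares have four edges; an exchange would leave a triangle
  sq <- square_fixture()
  eds <- tissue_edges(sq)
  ki <- which(!eds$margin)[1L]
  expect_warning(t2 <- t1_transition(sq, eds$v1[ki], eds$v2[ki], 0.1),
                 "four edges")
  expect_false(attr(t2, "did_t1"))
})

test_that("collapsed margin edges fuse into a margin vertex", {
  tt <- hex_strip(2, 2)
  ed <- tissue_edges(tt)
  k <- which(ed$margin & lengths(tt$cells)[ed$c1] >= 5L)[1L]
  t2 <- merge_margin_edge(tt, ed$v1[k], ed$v2[k])
  expect_true(attr(t2, "did_merge"))
  audit_tissue(t2)
  expect_equal(length(t2$cells[[ed$c1[k]]]),
               length(tt$cells[[ed$c1[k]]]) - 1L)
})
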