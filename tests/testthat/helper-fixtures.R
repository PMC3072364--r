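## Shared fixtures and independent oracles for the test suite.

## A "flower": one central hexagon surrounded by six hexagons. Built from a
## 3x3 block; the center cell of the block has six neighbors there, so we
## just relabel ids: returns the tissue plus the center cell id.
flower_fixture <- function() {
  tt <- hex_strip(3, 3)
  ctr <- cell_centroids(tt)
  mid <- which.min(rowSums((ctr - matrix(colMeans(ctr), nrow(ctr), 2,
                                         byrow = TRUE))^2))
  list(tissue = tt, center = mid)
}

## Two-cell horizontal chain (one anterior, one posterior).
two_cell_fixture <- function() hex_strip(1, 2)

## A 2 x 2 tissue of unit squares with a straight vertical A/P interface;
## used where exact interface straightness matters.
square_fixture <- function() {
  xy <- rbind(
    c(0, 0), c(1, 0), c(2, 0),
    c(0, 1), c(1, 1), c(2, 1),
    c(0, 2), c(1, 2), c(2, 2)
  )
  cells <- list(
    c(1L, 2L, 5L, 4L), c(2L, 3L, 6L, 5L),
    c(4L, 5L, 8L, 7L), c(5L, 6L, 9L, 8L)
  )
  new_tissue(xy, cells, compartment = c(1L, 2L, 1L, 2L))
}

## Central finite-difference gradient of the total energy (independent of
## the analytic gradient path).
fd_gradient <- function(tissue, params, factors = NULL, h = 1e-6) {
  f <- function(v) {
    t2 <- tissue
    t2$xy <- matrix(v, ncol = 2)
    tissue_energy(t2, params, factors)$total
  }
  x0 <- as.numeric(tissue$xy)
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  matrix(g, ncol = 2)
}

## Monolithic integration of the full coupled system (diffusion + kinetics,
## no operator splitting) with deSolve; the independent oracle for the
## compiled split integrator. `tissue` must be small (n cells).
monolithic_steady <- function(tissue, params, t_end = 4000) {
  fw <- wingvertex:::fv_weights(tissue)
  areas <- cell_areas(tissue)
  n <- n_cells(tissue)
  isA <- tissue$compartment == 1L
  g <- c(1, 0, 2)[tissue$genotype + 1L]
  p <- as.numeric(params)
  names(p) <- names(unclass(params))
  rhs <- function(t, y, parms) {
    m <- matrix(y, n, 7)
    d <- wingvertex:::kinetics_rhs(m, isA, g, params)
    ## add diffusive Hh exchange
    hh <- m[, 1L]
    q <- p[["D"]] * fw$w * (hh[fw$c2] - hh[fw$c1])
    flux <- rep(0, n)
    for (k in seq_along(q)) {
      flux[fw$c1[k]] <- flux[fw$c1[k]] + q[k]
      flux[fw$c2[k]] <- flux[fw$c2[k]] - q[k]
    }
    d[, 1L] <- d[, 1L] + flux / areas
    list(as.numeric(d))
  }
  out <- deSolve::ode(y = as.numeric(tissue$conc), times = c(0, t_end),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  matrix(out[nrow(out), -1L], n, 7, dimnames = list(NULL, wingvertex:::SPECIES))
}

## Scaled-down clone and control simulations shared across test files.
## Cached per session so several test blocks can reuse the same runs.
sim_cache <- new.env(parent = emptyenv())

cached_runs <- function(key, maker) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- maker()
  sim_cache[[key]]
}
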