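## Planar vertex-model mesh: construction, geometry queries, validity audit.
##
## A `tissue` is a list with components
##   xy          : V x 2 matrix of vertex positions (units of sqrt(A0), A0 = 1)
##   cells       : list of integer vectors, counterclockwise vertex cycles
##   compartment : integer per cell, 1 = anterior, 2 = posterior
##   genotype    : integer per cell, 0 background / 1 smo_mutant / 2 twin_spot
##   clone_id    : integer per cell (NA outside clones)
##   conc        : n_cells x 7 concentration matrix (see `SPECIES`)
##   target_area : per-cell target-area multiplier (1 = A0)
## Cell ids are list indices; compartment and genotype are heritable and never
## rewritten after assignment (divisions copy them to both daughters).

#' Construct a tissue object from its components
#'
#' Low-level constructor; most users will call [build_initial_grid()] or
#' [hex_strip()] instead. Vertex cycles must be counterclockwise simple
#' polygons sharing vertices with their neighbors.
#'
#' @param xy numeric matrix (V x 2) of vertex positions, in units of
#'   \eqn{\sqrt{A_0}} where \eqn{A_0} is the cell target area.
#' @param cells list of integer vertex cycles (counterclockwise).
#' @param compartment integer vector (1 = anterior, 2 = posterior), recycled.
#' @param genotype integer vector (0 background, 1 smo mutant, 2 twin spot).
#' @param clone_id optional integer clone labels (NA = no clone).
#' @param conc optional n x 7 concentration matrix; defaults to all zero
#'   (the simulation initializes every species at zero concentration).
#' @param target_area per-cell target-area multipliers, default 1.
#' @return An object of class `tissue`.
#' @export
new_tissue <- function(xy, cells, compartment = 1L, genotype = 0L,
                       clone_id = NA_integer_, conc = NULL,
                       target_area = 1) {
  n <- length(cells)
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  dimnames(xy) <- NULL
  if (ncol(xy) != 2L) stop("xy must have two columns")
  cells <- lapply(cells, as.integer)
  if (is.null(conc)) {
    conc <- matrix(0, n, length(SPECIES), dimnames = list(NULL, SPECIES))
  } else {
    conc <- as.matrix(conc)
    if (ncol(conc) != length(SPECIES)) stop("conc must have 7 columns")
    colnames(conc) <- SPECIES
  }
  structure(list(
    xy = xy,
    cells = cells,
    compartment = rep_len(as.integer(compartment), n),
    genotype = rep_len(as.integer(genotype), n),
    clone_id = rep_len(as.integer(clone_id), n),
    conc = conc,
    target_area = rep_len(as.numeric(target_area), n)
  ), class = "tissue")
}

#' Number of cells in a tissue
#' @param tissue a `tissue` object.
#' @return Integer cell count.
#' @export
n_cells <- function(tissue) length(tissue$cells)

#' Edge table of a tissue
#'
#' Derives the undirected edge list from the cell vertex cycles. Every
#' internal edge borders exactly two cells, every margin edge exactly one;
#' an edge shared by more than two cells signals a corrupted mesh.
#'
#' @param tissue a `tissue` object.
#' @return A data frame with columns `v1`, `v2` (vertex ids, `v1 < v2`),
#'   `c1`, `c2` (incident cell ids, `c2` is `NA` for margin edges) and
#'   `margin` (logical).
#' @export
tissue_edges <- function(tissue) {
  cyc <- tissue$cells
  nv <- lengths(cyc)
  from <- unlist(cyc, use.names = FALSE)
  ends <- cumsum(nv)
  nxt <- seq_along(from) + 1L
  nxt[ends] <- ends - nv + 1L
  to <- from[nxt]
  cell <- rep.int(seq_along(cyc), nv)
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- a * 2^24 + b  # exact for vertex ids < 2^24
  o <- order(key, method = "radix")
  key <- key[o]
  cell <- cell[o]
  a <- a[o]
  b <- b[o]
  first <- !duplicated(key)
  idx <- which(first)
  count <- diff(c(idx, length(key) + 1L))
  if (any(count > 2L)) stop("edge shared by more than two cells; invalid mesh")
  c2 <- rep(NA_integer_, length(idx))
  two <- count == 2L
  c2[two] <- cell[idx[two] + 1L]
  structure(list(v1 = a[idx], v2 = b[idx], c1 = cell[idx], c2 = c2,
                 margin = !two),
            class = "data.frame", row.names = c(NA_integer_, -length(idx)))
}

## Shoelace area of one polygon given as a coordinate matrix (CCW positive).
poly_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

poly_perimeter <- function(p) {
  dx <- diff(c(p[, 1L], p[1L, 1L]))
  dy <- diff(c(p[, 2L], p[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

## Area centroid of a simple polygon.
poly_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Area, perimeter and centroid of one cell
#'
#' @param tissue a `tissue` object.
#' @param cell cell id.
#' @return List with `area` (shoelace, positive for a valid cell),
#'   `perimeter` and `centroid` (length-2 vector).
#' @export
cell_geometry <- function(tissue, cell) {
  if (cell < 1L || cell > n_cells(tissue)) stop("no such cell: ", cell)
  cyc <- tissue$cells[[cell]]
  p <- tissue$xy[cyc, , drop = FALSE]
  a <- poly_area(p)
  if (!is.finite(a) || a <= 0) {
    stop("cell ", cell, " has non-positive area; invalid mesh state")
  }
  list(area = a, perimeter = poly_perimeter(p), centroid = poly_centroid(p))
}

#' Per-cell areas
#' @param tissue a `tissue` object.
#' @return Numeric vector of shoelace areas.
#' @export
cell_areas <- function(tissue) {
  cell_geom_cpp(tissue$xy, unlist(tissue$cells, use.names = FALSE) - 1L,
                c(0L, cumsum(lengths(tissue$cells))))$area
}

#' Per-cell area centroids
#' @param tissue a `tissue` object.
#' @return n x 2 matrix of centroids.
#' @export
cell_centroids <- function(tissue) {
  cell_geom_cpp(tissue$xy, unlist(tissue$cells, use.names = FALSE) - 1L,
                c(0L, cumsum(lengths(tissue$cells))))$centroid
}

## Outline polygon of the tissue: margin edges stitched into a cycle.
## Returns a coordinate matrix (CCW).
tissue_outline <- function(tissue) {
  ed <- tissue_edges(tissue)
  ed <- ed[ed$margin, , drop = FALSE]
  ## directed margin edges with the tissue on the left: recover orientation
  ## from the owning cell's cycle (cell keeps its own CCW orientation).
  fr <- integer(nrow(ed)); to <- integer(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    cyc <- tissue$cells[[ed$c1[i]]]
    k <- match(ed$v1[i], cyc)
    nxt <- cyc[if (k == length(cyc)) 1L else k + 1L]
    if (nxt == ed$v2[i]) { fr[i] <- ed$v1[i]; to[i] <- ed$v2[i] }
    else { fr[i] <- ed$v2[i]; to[i] <- ed$v1[i] }
  }
  nxt_of <- setNames(to, fr)
  start <- fr[1L]
  path <- integer(length(fr))
  cur <- start
  for (i in seq_along(fr)) {
    path[i] <- cur
    cur <- nxt_of[[as.character(cur)]]
    if (is.null(cur)) stop("tissue outline is not a closed cycle")
  }
  if (cur != start) stop("tissue outline is not a single closed cycle")
  tissue$xy[path, , drop = FALSE]
}

#' Audit mesh invariants
#'
#' Checks the structural invariants of the planar cell complex: every edge
#' borders one (margin) or two (internal) cells, all cell polygons have
#' positive area and no repeated vertices, the Euler relation
#' \eqn{V - E + F = 1} holds (outer face excluded), and the cell areas tile
#' the outline polygon without gaps or overlaps.
#'
#' @param tissue a `tissue` object.
#' @param tol relative tolerance for the area-tiling check.
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
audit_tissue <- function(tissue, tol = 1e-9) {
  ed <- tissue_edges(tissue)  # errors if any edge has > 2 cells
  v_used <- sort(unique(unlist(tissue$cells, use.names = FALSE)))
  V <- length(v_used)
  E <- nrow(ed)
  F <- n_cells(tissue)
  if (V - E + F != 1L) {
    stop(sprintf("Euler relation violated: V - E + F = %d - %d + %d = %d != 1",
                 V, E, F, V - E + F))
  }
  for (i in seq_len(F)) {
    cyc <- tissue$cells[[i]]
    if (anyDuplicated(cyc)) stop("cell ", i, " repeats a vertex")
    if (length(cyc) < 3L) stop("cell ", i, " has fewer than 3 vertices")
    a <- poly_area(tissue$xy[cyc, , drop = FALSE])
    if (!is.finite(a) || a <= 0) stop("cell ", i, " has non-positive area")
  }
  n <- length(tissue$cells)
  stopifnot(
    length(tissue$compartment) == n, length(tissue$genotype) == n,
    length(tissue$clone_id) == n, nrow(tissue$conc) == n,
    length(tissue$target_area) == n
  )
  a_cells <- sum(cell_areas(tissue))
  a_out <- poly_area(tissue_outline(tissue))
  if (abs(a_cells - a_out) > tol * a_out) {
    stop(sprintf("cells do not tile the outline: sum %.12g vs outline %.12g",
                 a_cells, a_out))
  }
  invisible(TRUE)
}

## Edge length implied by unit cell area for a regular hexagon:
## A0 = (3*sqrt(3)/2) l^2  =>  l = sqrt(2 / (3 sqrt(3))).
hex_edge_unit_area <- function() sqrt(2 / (3 * sqrt(3)))

## Internal hexagonal-lattice builder: flat-top hexagons in column-major
## layout (columns aligned in x), `dims = c(ncol, nrow)`. Column parity
## staggers the y offset; shared vertices are deduplicated on the half-step
## lattice. The interface between two column blocks is then a vertical
## zigzag of slant edges, the straightest interface a hexagonal lattice
## admits.
hex_lattice <- function(dims, edge_length = hex_edge_unit_area()) {
  nc <- dims[1L]; nr <- dims[2L]
  R <- edge_length
  h <- sqrt(3) / 2 * R
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]  # flat-top: vertex at angle 0
  vx0 <- R * cos(ang)
  vy0 <- R * sin(ang)
  keys <- character(0)
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  xy <- matrix(0, 0, 2)
  nvert <- 0L
  cells <- vector("list", nc * nr)
  coords <- matrix(0, nc * nr, 2)
  k <- 0L
  xs <- numeric(0); ys <- numeric(0)
  for (col in seq_len(nc) - 1L) {
    for (row in seq_len(nr) - 1L) {
      cx <- 1.5 * R * col
      cy <- sqrt(3) * R * row + (col %% 2L) * h
      k <- k + 1L
      coords[k, ] <- c(cx, cy)
      cyc <- integer(6)
      for (j in 1:6) {
        x <- cx + vx0[j]
        y <- cy + vy0[j]
        key <- paste(round(x / (R / 2)), round(y / h))
        id <- vmap[[key]]
        if (is.null(id)) {
          nvert <- nvert + 1L
          id <- nvert
          vmap[[key]] <- id
          xs[nvert] <- x
          ys[nvert] <- y
        }
        cyc[j] <- id
      }
      cells[[k]] <- cyc
    }
  }
  list(xy = cbind(xs, ys), cells = cells, centers = coords)
}

## Pick (ncol, nrow) for n cells: exact divisor pair whose physical aspect
## ratio (width/height) is closest to 1, preferring an even column count so
## the A/P split falls between columns.
grid_dims <- function(n) {
  div <- which(n %% seq_len(n) == 0L)
  best <- NULL
  best_score <- Inf
  for (nc in div) {
    nr <- n %/% nc
    aspect <- (1.5 * nc) / (sqrt(3) * nr)
    score <- abs(log(aspect)) + if (nc %% 2L == 0L) 0 else 0.15
    if (score < best_score) { best_score <- score; best <- c(nc, nr) }
  }
  best
}

#' Build the deterministic initial cell grid
#'
#' Places `n_cells` regular hexagons in a rectangular block (the same
#' starting formation every time), split into a left anterior and a right
#' posterior compartment of near-equal size along a vertical interface:
#' cells whose centroid lies right of the median centroid x are posterior.
#'
#' @param n_cells number of cells (default 220, the standard starting
#'   configuration).
#' @param edge_length hexagon edge length; the default gives unit cell area.
#' @param dims optional `c(ncol, nrow)` overriding the automatic near-square
#'   factorization of `n_cells`.
#' @return A `tissue` with zero initial concentrations.
#' @export
build_initial_grid <- function(n_cells = 220L, edge_length = hex_edge_unit_area(),
                               dims = NULL) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (edge_length <= 0) stop("edge_length must be > 0")
  if (is.null(dims)) dims <- grid_dims(n_cells)
  if (prod(dims) != n_cells) stop("dims do not multiply to n_cells")
  lat <- hex_lattice(dims, edge_length)
  xmed <- median(lat$centers[, 1L])
  comp <- ifelse(lat$centers[, 1L] > xmed, COMP_P, COMP_A)
  if (n_cells == 1L) comp <- COMP_P  # a lone cell: make it a producer
  new_tissue(lat$xy, lat$cells, compartment = comp)
}

#' Build a fixed hexagonal strip fixture
#'
#' A `rows` x `cols` block of regular hexagons with the left `cols/2`
#' columns anterior and the rest posterior. Used for unit tests and for
#' signaling/tension calibration on a non-growing mesh.
#'
#' @param rows,cols strip dimensions (cells).
#' @param edge_length hexagon edge length (default: unit area).
#' @return A `tissue`.
#' @export
hex_strip <- function(rows, cols, edge_length = hex_edge_unit_area()) {
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  build_initial_grid(rows * cols, edge_length, dims = c(cols, rows))
}

#' @export
print.tissue <- function(x, ...) {
  ed <- tissue_edges(x)
  cat(sprintf("<tissue> %d cells, %d vertices, %d edges (%d margin)\n",
              n_cells(x), nrow(x$xy), nrow(ed), sum(ed$margin)))
  tab <- table(factor(comp_names[x$compartment], levels = comp_names))
  cat(sprintf("  compartments: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  g <- table(factor(geno_names[x$genotype + 1L], levels = geno_names))
  if (sum(g[-1L]) > 0) {
    cat(sprintf("  genotypes: %s\n",
                paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.tissue <- function(object, ...) {
  a <- cell_areas(object)
  cat(sprintf("cells: %d   mean area: %.4f   sd: %.4f\n",
              n_cells(object), mean(a), sd(a)))
  cat("polygon classes:\n")
  print(table(lengths(object$cells)))
  invisible(object)
}

#' Plot a tissue
#'
#' Draws the cell polygons, colored by compartment/genotype, optionally
#' shaded by a per-cell quantity such as a TMx concentration.
#'
#' @param x a `tissue`.
#' @param fill optional numeric per-cell vector to shade by (overrides the
#'   label coloring).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.tissue <- function(x, fill = NULL, ...) {
  rng <- apply(x$xy, 2L, range)
  graphics::plot(NA, xlim = rng[, 1L], ylim = rng[, 2L], asp = 1,
                 xlab = "x", ylab = "y", ...)
  if (is.null(fill)) {
    col <- ifelse(x$compartment == COMP_A, "#9ecae1", "#a1d99b")
    col[x$genotype == GENO_SMO_MUTANT] <- "#de2d26"
    col[x$genotype == GENO_TWIN_SPOT] <- "#31a354"
  } else {
    f <- (fill - min(fill)) / max(1e-12, diff(range(fill)))
    col <- grDevices::rgb(1, 1 - f, 1 - 0.6 * f)
  }
  for (i in seq_len(n_cells(x))) {
    graphics::polygon(x$xy[x$cells[[i]], , drop = FALSE], col = col[i],
                      border = "grey30", lwd = 0.4)
  }
  invisible(x)
}
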