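## Morphometrics: clone shape, clone position and boundary quality.

## A/P boundary edge subset. With `background_only`, edges touching clone
## cells are excluded, so the polyline tracks the interface between the
## unlabeled anterior and posterior populations even after clones migrate.
ap_boundary_edges <- function(tissue, background_only = FALSE) {
  ed <- tissue_edges(tissue)
  ie <- ed[!ed$margin, , drop = FALSE]
  comp <- tissue$compartment
  sel <- comp[ie$c1] != comp[ie$c2]
  if (background_only) {
    g <- tissue$genotype
    sel <- sel & g[ie$c1] == GENO_BACKGROUND & g[ie$c2] == GENO_BACKGROUND
  }
  ie[sel, , drop = FALSE]
}

#' Boundary roughness
#'
#' Total length of the A/P interface divided by the largest distance
#' between any two of its vertices: 1 for a perfectly straight interface,
#' growing as the interface wiggles, folds or fragments.
#'
#' @param tissue a `tissue`.
#' @param background_only restrict to interface edges between unlabeled
#'   cells (see clones)?
#' @return Dimensionless roughness >= 1 (on an ideal straight interface).
#' @export
boundary_roughness <- function(tissue, background_only = FALSE) {
  be <- ap_boundary_edges(tissue, background_only)
  if (!nrow(be)) stop("tissue has no A/P boundary edges")
  p1 <- tissue$xy[be$v1, , drop = FALSE]
  p2 <- tissue$xy[be$v2, , drop = FALSE]
  total <- sum(sqrt(rowSums((p2 - p1)^2)))
  pts <- unique(rbind(p1, p2))
  span <- max(stats::dist(pts))
  total / span
}

## connected components of a set of cells under edge adjacency
clone_components <- function(tissue, cells) {
  adj <- cell_adjacency(tissue)
  comp <- setNames(rep(NA_integer_, length(cells)), cells)
  k <- 0L
  for (c0 in cells) {
    if (!is.na(comp[[as.character(c0)]])) next
    k <- k + 1L
    queue <- c0
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      key <- as.character(v)
      if (!is.na(comp[[key]])) next
      comp[[key]] <- k
      queue <- c(queue, intersect(adj[[v]], cells))
    }
  }
  split(cells, comp[as.character(cells)])
}

#' Outer outline polygon of a clone
#'
#' Boundary edges of the union of the clone's member cells, stitched into
#' cycles; the outermost cycle is returned, so interior holes do not
#' contribute to the perimeter (matching mask-based shape measurement).
#'
#' @param tissue a `tissue`.
#' @param clone_id clone label to outline.
#' @return Coordinate matrix of the outline polygon (counterclockwise).
#' @export
clone_outline <- function(tissue, clone_id) {
  members <- which(tissue$clone_id == clone_id)
  members <- members[!is.na(tissue$clone_id[members])]
  if (!length(members)) stop("empty clone: ", clone_id)
  cc <- clone_components(tissue, members)
  if (length(cc) > 1L) {
    stop("clone ", clone_id, " is disconnected: components of sizes ",
         paste(lengths(cc), collapse = ", "))
  }
  outline_of_cells(tissue, members)
}

## outline of an arbitrary edge-connected cell set
outline_of_cells <- function(tissue, members) {
  inset <- logical(n_cells(tissue))
  inset[members] <- TRUE
  ## directed boundary edges (member cell on the left => outer cycle CCW)
  fr <- integer(0); to <- integer(0)
  ed <- tissue_edges(tissue)
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(ed))) {
    c1 <- ed$c1[k]; c2 <- ed$c2[k]
    n_in <- inset[c1] + (!is.na(c2) && inset[c2])
    if (n_in != 1L) next
    own <- if (inset[c1]) c1 else c2
    cyc <- tissue$cells[[own]]
    i <- match(ed$v1[k], cyc)
    nxt <- cyc[if (i == length(cyc)) 1L else i + 1L]
    if (nxt == ed$v2[k]) { fr <- c(fr, ed$v1[k]); to <- c(to, ed$v2[k]) }
    else { fr <- c(fr, ed$v2[k]); to <- c(to, ed$v1[k]) }
  }
  used <- logical(length(fr))
  cycles <- list()
  for (s in seq_along(fr)) {
    if (used[s]) next
    path <- integer(0)
    cur <- s
    repeat {
      used[cur] <- TRUE
      path <- c(path, fr[cur])
      nxts <- which(!used & fr == to[cur])
      if (!length(nxts)) break
      cur <- nxts[[1L]]
    }
    cycles[[length(cycles) + 1L]] <- path
  }
  areas <- vapply(cycles, function(cyc) {
    poly_area(tissue$xy[cyc, , drop = FALSE])
  }, numeric(1))
  tissue$xy[cycles[[which.max(areas)]], , drop = FALSE]
}

#' Isoperimetric roundness of a polygon
#'
#' \eqn{R = 4\pi A / L^2}: 1 for a circle (isoperimetric equality), smaller
#' for every other shape; invariant under rigid motions and uniform
#' scaling.
#'
#' @param polygon coordinate matrix of a simple polygon.
#' @return Roundness in (0, 1].
#' @export
roundness <- function(polygon) {
  a <- abs(poly_area(polygon))
  l <- poly_perimeter(polygon)
  if (!is.finite(a) || a <= 0 || l <= 0) stop("degenerate polygon")
  4 * pi * a / l^2
}

## mean nearest-centroid spacing of a unit-area hexagonal packing; used as
## the reference "cell diameter" for physical calibration
cell_diameter <- function(tissue) {
  sqrt(2 * mean(cell_areas(tissue)) / sqrt(3))
}

## minimum distance from point p to the segment set (p1[i,], p2[i,])
dist_to_segments <- function(p, p1, p2) {
  d <- p2 - p1
  len2 <- rowSums(d^2)
  t <- ((p[1L] - p1[, 1L]) * d[, 1L] + (p[2L] - p1[, 2L]) * d[, 2L]) /
    pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  px <- p1[, 1L] + t * d[, 1L]
  py <- p1[, 2L] + t * d[, 2L]
  i <- which.min((p[1L] - px)^2 + (p[2L] - py)^2)
  list(dist = sqrt((p[1L] - px[i])^2 + (p[2L] - py[i])^2), edge = i)
}

#' Signed distance of a clone's center of mass to the A/P boundary
#'
#' Euclidean distance from the clone's area-weighted center of mass to the
#' polyline of A/P interface edges (between unlabeled cells), converted to
#' micrometers; positive on the anterior side. The physical scale is set
#' by `um_per_cell_diameter` micrometers per mean cell diameter.
#'
#' @param tissue a `tissue`.
#' @param clone_id clone label.
#' @param um_per_cell_diameter calibration (default 2).
#' @return Signed distance in micrometers.
#' @export
boundary_distance <- function(tissue, clone_id, um_per_cell_diameter = 2) {
  members <- which(!is.na(tissue$clone_id) & tissue$clone_id == clone_id)
  if (!length(members)) stop("empty clone: ", clone_id)
  boundary_distance_cells(tissue, members, um_per_cell_diameter)
}

#' Per-clone morphometric records
#'
#' One row per clone: genotype, compartment of origin, member count, area,
#' outer-outline perimeter, isoperimetric roundness and signed boundary
#' distance in micrometers.
#'
#' @param tissue a `tissue` containing labeled clones.
#' @param um_per_cell_diameter physical calibration.
#' @return Data frame of clone records (class `clone_records`).
#' @export
clone_records <- function(tissue, um_per_cell_diameter = 2) {
  ids <- sort(unique(tissue$clone_id[!is.na(tissue$clone_id)]))
  rows <- lapply(ids, function(id) {
    members <- which(!is.na(tissue$clone_id) & tissue$clone_id == id)
    ## a clone id labels one mutant + one twin lineage: split by genotype
    lapply(split(members, tissue$genotype[members]), function(mem) {
      cc <- clone_components(tissue, mem)
      ## mitotic clones can fragment during growth; measure the largest piece
      mem <- cc[[which.max(lengths(cc))]]
      out <- outline_of_cells(tissue, mem)
      a <- poly_area(out)
      l <- poly_perimeter(out)
      data.frame(
        clone_id = id,
        genotype = geno_names[tissue$genotype[mem[1L]] + 1L],
        compartment = comp_names[tissue$compartment[mem[1L]]],
        n_cells = length(mem),
        area = a, perimeter = l,
        roundness = 4 * pi * a / l^2,
        distance_um = tryCatch(
          boundary_distance_cells(tissue, mem, um_per_cell_diameter),
          error = function(e) NA_real_)
      )
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  structure(out, class = c("clone_records", "data.frame"))
}

## boundary_distance for an explicit member set (internal). The distance
## is measured to the interface between the unlabeled A and P populations;
## the side is decided by the compartment of the background cells that
## surround the clone (robust even where clones sit on the interface and
## deplete it of background-background segments), falling back to the
## nearest segment's incident cells for genuinely straddling clones.
boundary_distance_cells <- function(tissue, members, um_per_cell_diameter = 2) {
  be <- ap_boundary_edges(tissue, background_only = TRUE)
  if (!nrow(be)) stop("tissue has no A/P boundary edges")
  areas <- cell_areas(tissue)[members]
  ctr <- cell_centroids(tissue)[members, , drop = FALSE]
  com <- colSums(ctr * areas) / sum(areas)
  hit <- dist_to_segments(com, tissue$xy[be$v1, , drop = FALSE],
                          tissue$xy[be$v2, , drop = FALSE])
  nb <- setdiff(unique(unlist(cell_adjacency(tissue)[members],
                              use.names = FALSE)), members)
  nb <- nb[tissue$genotype[nb] == GENO_BACKGROUND]
  frac_a <- if (length(nb)) mean(tissue$compartment[nb] == COMP_A) else 0.5
  if (frac_a >= 0.6) {
    side <- COMP_A
  } else if (frac_a <= 0.4) {
    side <- COMP_P
  } else {
    k <- hit$edge
    cc <- cell_centroids(tissue)[c(be$c1[k], be$c2[k]), , drop = FALSE]
    dd <- sqrt(rowSums((cc - rep(com, each = 2))^2))
    side <- tissue$compartment[c(be$c1[k], be$c2[k])][which.min(dd)]
  }
  sgn <- if (side == COMP_A) 1 else -1
  sgn * hit$dist / cell_diameter(tissue) * um_per_cell_diameter
}

#' Roundness-versus-distance trend analysis
#'
#' For each genotype-by-compartment group, filters clones closer than
#' `min_distance` micrometers to the boundary (excluding migrating clones,
#' as in mask-based measurements), then fits roundness against absolute
#' boundary distance by ordinary least squares (slope, intercept, two-sided
#' t-test p-value for slope = 0) and computes a sliding-window moving
#' average.
#'
#' @param records a [clone_records()] data frame (rows from several runs
#'   can be concatenated).
#' @param min_distance exclusion radius around the boundary (um).
#' @param window,step moving-average window and step (um).
#' @return List of class `trend_result` keyed by `genotype.compartment`,
#'   each with `n`, `slope`, `intercept`, `p_value` and `moving_average`
#'   (`distance`, `mean_roundness`, `n`).
#' @export
roundness_trend <- function(records, min_distance = 5, window = 10, step = 2) {
  records <- records[!is.na(records$distance_um) &
                       abs(records$distance_um) >= min_distance, , drop = FALSE]
  if (nrow(records) < 3L) {
    stop("fewer than 3 clones remain after distance filtering")
  }
  groups <- split(records,
                  interaction(records$genotype, records$compartment, drop = TRUE))
  out <- lapply(groups, function(g) {
    if (nrow(g) < 3L) {
      stop("fewer than 3 clones after distance filtering in group ",
           g$genotype[1L], "/", g$compartment[1L])
    }
    d <- abs(g$distance_um)
    fit <- lm(roundness ~ d, data = data.frame(roundness = g$roundness, d = d))
    sm <- summary(fit)$coefficients
    centers <- seq(min(d), max(d), by = step)
    ma <- do.call(rbind, lapply(centers, function(x0) {
      sel <- abs(d - x0) <= window / 2
      if (!any(sel)) return(NULL)
      data.frame(distance = x0, mean_roundness = mean(g$roundness[sel]),
                 n = sum(sel))
    }))
    list(n = nrow(g),
         slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         p_value = if (nrow(sm) >= 2L) sm[2L, 4L] else NA_real_,
         moving_average = ma)
  })
  structure(out, class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  for (nm in names(x)) {
    g <- x[[nm]]
    cat(sprintf("%-28s n = %3d  slope = %+.5f /um  p = %.3g\n",
                nm, g$n, g$slope, g$p_value))
  }
  invisible(x)
}

#' Polygon-class statistics and boundary-row areas
#'
#' Polygon-number histogram, mean cell area per polygon class normalized to
#' the tissue mean, and mean areas of the first and second cell rows
#' flanking the A/P boundary (A1/A2 anterior, P1/P2 posterior) relative to
#' their compartment bulk. Margin cells are excluded (their shapes are
#' dominated by the open boundary).
#'
#' @param tissue a `tissue` (at least ~50 cells for stable statistics).
#' @return List with `class_freq` (named proportions), `class_area`
#'   (named mean normalized areas), `rows` (data frame: row label, mean
#'   normalized area, n) and `n` (cells used).
#' @export
polygon_stats <- function(tissue) {
  ed <- tissue_edges(tissue)
  margin_cells <- unique(ed$c1[ed$margin])
  use <- setdiff(seq_len(n_cells(tissue)), margin_cells)
  nedges <- lengths(tissue$cells)[use]
  areas <- cell_areas(tissue)
  na <- areas[use] / mean(areas[use])
  class_freq <- table(nedges) / length(nedges)
  class_area <- tapply(na, nedges, mean)
  rows <- rows_from_boundary(tissue)
  comp <- tissue$compartment
  lab <- rep(NA_character_, n_cells(tissue))
  lab[comp == COMP_A & rows == 1L] <- "A1"
  lab[comp == COMP_A & rows == 2L] <- "A2"
  lab[comp == COMP_P & rows == 1L] <- "P1"
  lab[comp == COMP_P & rows == 2L] <- "P2"
  lab[comp == COMP_A & rows > 2L] <- "A_bulk"
  lab[comp == COMP_P & rows > 2L] <- "P_bulk"
  keep <- !is.na(lab) & seq_len(n_cells(tissue)) %in% use
  rowtab <- do.call(rbind, lapply(split(which(keep), lab[keep]), function(ix) {
    data.frame(row = lab[ix[1L]],
               mean_area = mean(areas[ix]) / mean(areas[use]),
               n = length(ix))
  }))
  rownames(rowtab) <- NULL
  list(class_freq = class_freq, class_area = class_area, rows = rowtab,
       n = length(use))
}
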