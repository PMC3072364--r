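## Topology operations: cell division and T1 neighbor exchange.
##
## Both operations rewrite vertex cycles in place and must leave the mesh
## invariants (see `audit_tissue`) intact. Division appends vertices and one
## cell; the mother's slot is reused by the first daughter so that all other
## cell ids remain stable.

## Insert vertex `w` into cell `cell`'s cycle between adjacent vertices
## `va`, `vb` (in either order as they appear in the cycle).
insert_vertex_between <- function(cells, cell, va, vb, w) {
  cyc <- cells[[cell]]
  m <- length(cyc)
  ka <- match(va, cyc)
  if (is.na(ka)) stop("vertex not in cell cycle")
  after <- cyc[if (ka == m) 1L else ka + 1L]
  before <- cyc[if (ka == 1L) m else ka - 1L]
  if (after == vb) {
    cells[[cell]] <- append(cyc, w, after = ka)
  } else if (before == vb) {
    cells[[cell]] <- append(cyc, w, after = ka - 1L)
  } else {
    stop("vertices not adjacent in cell cycle")
  }
  cells
}

#' Divide a cell through its centroid
#'
#' Splits `cell` by a straight line through its area centroid at angle
#' `angle`, inserting two new vertices on the crossed boundary edges. Both
#' daughters inherit the mother's compartment, genotype, clone id and
#' concentrations (so total molecule amounts, concentration times area, are
#' conserved), and both reset their target area to \eqn{A_0}. The division
#' line must cross the polygon boundary exactly twice and not within
#' `eps` of an existing vertex; otherwise an error of class
#' `wingvertex_retry` is signaled and the caller should re-draw the angle.
#'
#' @param tissue a `tissue`.
#' @param cell id of the cell to divide.
#' @param angle division-line angle in radians (drawn uniformly by callers
#'   simulating randomly oriented divisions).
#' @param eps minimum admissible distance (as a fraction of the crossed edge
#'   length) between a new vertex and an existing one.
#' @return The updated `tissue`, with attribute `daughters` giving the two
#'   daughter cell ids (the first reuses the mother's id).
#' @export
divide_cell <- function(tissue, cell, angle, eps = 0.05) {
  cyc <- tissue$cells[[cell]]
  m <- length(cyc)
  p <- tissue$xy[cyc, , drop = FALSE]
  ctr <- poly_centroid(p)
  u <- c(cos(angle), sin(angle))
  ## signed distance of each cycle vertex from the division line
  s <- (p[, 1L] - ctr[1L]) * (-u[2L]) + (p[, 2L] - ctr[2L]) * u[1L]
  nxt <- c(2:m, 1L)
  crossing <- which(s * s[nxt] < 0)
  if (length(crossing) != 2L || any(s == 0)) {
    stop(structure(class = c("wingvertex_retry", "error", "condition"),
                   list(message = "division line does not cross the boundary exactly twice",
                        call = sys.call())))
  }
  ## daughters need >= 4 vertices: without T2 extrusion in the model, a
  ## triangular cell that later gets squeezed could not resolve topologically
  dj <- crossing[2L] - crossing[1L]
  if (dj < 2L || dj > m - 2L) {
    stop(structure(class = c("wingvertex_retry", "error", "condition"),
                   list(message = "division line would create a triangular daughter",
                        call = sys.call())))
  }
  tfrac <- s[crossing] / (s[crossing] - s[nxt[crossing]])
  if (any(tfrac < eps | tfrac > 1 - eps)) {
    stop(structure(class = c("wingvertex_retry", "error", "condition"),
                   list(message = "division line passes too close to a vertex",
                        call = sys.call())))
  }
  ## new vertex positions on the two crossed edges
  newpts <- p[crossing, , drop = FALSE] +
    tfrac * (p[nxt[crossing], , drop = FALSE] - p[crossing, , drop = FALSE])
  nv <- nrow(tissue$xy)
  w1 <- nv + 1L
  w2 <- nv + 2L
  tissue$xy <- rbind(tissue$xy, newpts)

  i <- crossing[1L]; j <- crossing[2L]
  vi1 <- cyc[i]; vi2 <- cyc[nxt[i]]
  vj1 <- cyc[j]; vj2 <- cyc[nxt[j]]

  ## insert the new vertices into the neighbor cells sharing the crossed edges
  ed <- tissue_edges(tissue)
  find_other <- function(a, b) {
    r <- ed[(ed$v1 == min(a, b)) & (ed$v2 == max(a, b)), ]
    other <- c(r$c1, r$c2)
    other <- other[!is.na(other) & other != cell]
    if (length(other)) other[[1L]] else NA_integer_
  }
  nb1 <- find_other(vi1, vi2)
  nb2 <- find_other(vj1, vj2)
  if (!is.na(nb1)) tissue$cells <- insert_vertex_between(tissue$cells, nb1, vi1, vi2, w1)
  if (!is.na(nb2)) tissue$cells <- insert_vertex_between(tissue$cells, nb2, vj1, vj2, w2)

  ## split the mother cycle: i < j always (crossing is sorted)
  d1 <- c(w1, cyc[(i + 1L):j], w2)
  d2 <- c(w2, if (j < m) cyc[(j + 1L):m], cyc[seq_len(i)], w1)

  new_id <- n_cells(tissue) + 1L
  tissue$cells[[cell]] <- d1
  tissue$cells[[new_id]] <- d2
  tissue$compartment[new_id] <- tissue$compartment[cell]
  tissue$genotype[new_id] <- tissue$genotype[cell]
  tissue$clone_id[new_id] <- tissue$clone_id[cell]
  tissue$conc <- rbind(tissue$conc, tissue$conc[cell, , drop = FALSE])
  tissue$target_area[cell] <- 1
  tissue$target_area[new_id] <- 1
  structure(tissue, daughters = c(cell, new_id))
}

## Third cell at vertex `v` besides the two given, or NA (margin vertex).
third_cell_at <- function(tissue, v, not) {
  hit <- which(vapply(tissue$cells, function(cyc) any(cyc == v), logical(1)))
  hit <- setdiff(hit, not)
  if (length(hit) == 1L) hit else NA_integer_
}

#' T1 neighbor exchange on a short edge
#'
#' Collapses the internal edge to its midpoint and re-extends it
#' perpendicular at length `new_length`, swapping adjacency: the two cells
#' formerly sharing the edge separate and the two cells formerly meeting it
#' only at an endpoint become neighbors. If one endpoint lies on the tissue
#' margin, the exchange instead brings the third cell at the interior
#' endpoint out to the margin (the re-extended edge becomes a margin edge).
#' Topologically forbidden exchanges (a participating cell would drop below
#' three edges, or both endpoints are margin vertices) leave the tissue
#' unchanged with a warning.
#'
#' @param tissue a `tissue`.
#' @param v1,v2 the edge's vertex ids.
#' @param new_length length of the re-extended edge (callers use a value
#'   slightly above the T1 trigger threshold).
#' @return Updated `tissue`; attribute `did_t1` is `TRUE` if the exchange
#'   was performed.
#' @export
t1_transition <- function(tissue, v1, v2, new_length) {
  ## locate the two cells sharing the edge, with orientation: c1 traverses
  ## v1 -> v2 (edge on its CCW cycle), c2 traverses v2 -> v1.
  c1 <- NA_integer_; c2 <- NA_integer_
  for (i in seq_len(n_cells(tissue))) {
    cyc <- tissue$cells[[i]]
    k <- match(v1, cyc)
    if (is.na(k)) next
    m <- length(cyc)
    if (cyc[if (k == m) 1L else k + 1L] == v2) c1 <- i
    else if (cyc[if (k == 1L) m else k - 1L] == v2) c2 <- i
  }
  if (is.na(c1) || is.na(c2)) {
    warning("T1 skipped: edge is not internal")
    return(structure(tissue, did_t1 = FALSE))
  }
  ## both cells keep >= 4 edges afterwards: triangles are excluded because
  ## a squeezed triangle could only resolve by T2 extrusion (not modeled)
  if (length(tissue$cells[[c1]]) < 5L || length(tissue$cells[[c2]]) < 5L) {
    warning("T1 skipped: a participating cell would drop below four edges")
    return(structure(tissue, did_t1 = FALSE))
  }
  ca <- third_cell_at(tissue, v1, c(c1, c2))
  cb <- third_cell_at(tissue, v2, c(c1, c2))
  if (is.na(ca) && !is.na(cb)) {
    ## margin endpoint must play the v2 role: swap (c1/c2 swap implicitly
    ## because c1 is defined by traversal direction)
    return(t1_transition(tissue, v2, v1, new_length))
  }
  if (is.na(ca) || (!is.na(cb) && ca == cb)) {
    warning("T1 skipped: junction topology does not admit an exchange")
    return(structure(tissue, did_t1 = FALSE))
  }
  ## cb may be NA: v2 lies on the tissue margin. The exchange then brings
  ## cell ca to the margin and the re-extended edge becomes a margin edge
  ## of ca; the cycle surgery below is identical except that there is no
  ## fourth cell to gain a vertex.
  a <- tissue$xy[v1, ]; b <- tissue$xy[v2, ]
  mid <- (a + b) / 2
  e <- b - a
  len <- sqrt(sum(e^2))
  if (len < .Machine$double.eps) e <- c(1, 0) else e <- e / len
  nrm <- c(-e[2L], e[1L])  # left normal: points into c1's side
  tissue$xy[v1, ] <- mid + nrm * new_length / 2
  tissue$xy[v2, ] <- mid - nrm * new_length / 2
  ## cycle surgery (c1 keeps v1, c2 keeps v2):
  tissue$cells[[c1]] <- setdiff(tissue$cells[[c1]], v2)
  tissue$cells[[c2]] <- setdiff(tissue$cells[[c2]], v1)
  ## ca gains v2 immediately before v1; cb gains v1 immediately before v2
  cyc <- tissue$cells[[ca]]
  k <- match(v1, cyc)
  tissue$cells[[ca]] <- append(cyc, v2, after = k - 1L)
  if (!is.na(cb)) {
    cyc <- tissue$cells[[cb]]
    k <- match(v2, cyc)
    tissue$cells[[cb]] <- append(cyc, v1, after = k - 1L)
  }
  structure(tissue, did_t1 = TRUE)
}

#' Merge a collapsed margin edge
#'
#' When a margin edge shrinks to (near) zero length the two margin
#' vertices are fused at their midpoint and the owning cell drops the
#' edge; the tissue outline shortens by one segment. This is the margin
#' counterpart of the T1 exchange for interior junctions. The merge is
#' refused (with a warning) if the owning cell has fewer than four
#' vertices or if another cell contains both endpoints.
#'
#' @param tissue a `tissue`.
#' @param v1,v2 vertex ids of the margin edge.
#' @return Updated `tissue`; attribute `did_merge` reports success.
#' @export
merge_margin_edge <- function(tissue, v1, v2) {
  own <- integer(0)
  with_v2 <- integer(0)
  for (i in seq_len(n_cells(tissue))) {
    cyc <- tissue$cells[[i]]
    has1 <- any(cyc == v1)
    has2 <- any(cyc == v2)
    if (has2) with_v2 <- c(with_v2, i)
    if (has1 && has2) own <- c(own, i)
  }
  if (length(own) != 1L) {
    warning("margin merge skipped: edge endpoints shared by ", length(own),
            " cells")
    return(structure(tissue, did_merge = FALSE))
  }
  if (length(tissue$cells[[own]]) < 5L) {
    warning("margin merge skipped: owning cell would drop below four edges")
    return(structure(tissue, did_merge = FALSE))
  }
  mid <- (tissue$xy[v1, ] + tissue$xy[v2, ]) / 2
  tissue$xy[v1, ] <- mid
  for (i in with_v2) {
    cyc <- tissue$cells[[i]]
    cyc[cyc == v2] <- v1
    ## drop the duplicate that arises in the owning cell
    dup <- which(cyc == v1)
    if (length(dup) > 1L) cyc <- cyc[-dup[2L]]
    tissue$cells[[i]] <- cyc
  }
  structure(tissue, did_merge = TRUE)
}

## Remove a fully collapsed cell -- or an edge-connected cluster of
## collapsed cells -- by fusing all of its vertices into one point
## (extrusion). Only invoked as a numerical safeguard by `relax` when
## cells have been squeezed below a small fraction of the target area and
## their junctions can no longer rearrange by T1; the removed cells'
## molecule content leaves the plane with them. Returns the tissue with
## attribute `did_t2`; cell ids above the removed cells shift down.
t2_collapse <- function(tissue, cells) {
  verts <- unique(unlist(tissue$cells[cells], use.names = FALSE))
  keep <- verts[1L]
  ## build candidate cycles for every other cell and verify validity first
  newcells <- tissue$cells
  for (i in seq_along(newcells)) {
    if (i %in% cells) next
    ci <- newcells[[i]]
    if (!any(ci %in% verts)) next
    ci[ci %in% verts] <- keep
    ## collapse consecutive duplicates (cyclically)
    r <- ci[c(ci[-1L], ci[1L]) != ci]
    if (length(r) < 4L || anyDuplicated(r)) {
      return(structure(tissue, did_t2 = FALSE))
    }
    newcells[[i]] <- r
  }
  ctr <- colMeans(tissue$xy[verts, , drop = FALSE])
  tissue$xy[keep, ] <- ctr
  tissue$cells <- newcells[-cells]
  tissue$compartment <- tissue$compartment[-cells]
  tissue$genotype <- tissue$genotype[-cells]
  tissue$clone_id <- tissue$clone_id[-cells]
  tissue$conc <- tissue$conc[-cells, , drop = FALSE]
  tissue$target_area <- tissue$target_area[-cells]
  structure(tissue, did_t2 = TRUE)
}
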