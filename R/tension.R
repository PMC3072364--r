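## TMx -> line-tension coupling.
##
## The conversion of per-cell TMx concentrations into per-edge tension
## scaling factors encodes two assumptions: (i) TMx molecules are recruited
## preferentially to interfaces offering more homotypic binding partners
## (each edge adopts the higher of the two adjacent cells' TMx-proportional
## bond values), and (ii) the per-cell pool of tension effectors is rate
## limiting (each cell's factors are normalized to unit mean over its own
## edges). The factors therefore depend only on TMx *ratios* between
## neighboring cells, never on absolute concentrations.

#' Compute per-edge line-tension scaling factors from a TMx field
#'
#' Four steps: (1) every cell assigns a bond value equal to its own TMx
#' concentration to each of its edges; (2) for an internal edge both cells
#' adopt the larger of the two bond values (margin edges keep the cell's
#' own value); (3) each cell divides its edge values by their unweighted
#' mean, so the factors of every cell average exactly to one; (4) the
#' effective per-edge factor is the mean of the one or two incident cells'
#' values.
#'
#' @param tissue a `tissue`.
#' @param tmx per-cell TMx concentrations (default: the tissue's TMx
#'   column). All values must be positive.
#' @param length_weighted if `TRUE`, the per-cell normalization in step (3)
#'   uses edge-length-weighted means (sensitivity variant; the default
#'   unweighted mean is the model used throughout).
#' @return An object of class `tension_factors`: a data frame of edges
#'   (`v1`, `v2`, `c1`, `c2`, `margin`) with per-incidence factors
#'   `lambda1`, `lambda2` (NA on margin edges) and the effective factor
#'   `lambda_bar`; the TMx field used is kept as attribute `tmx`.
#' @export
compute_factors <- function(tissue, tmx = tissue$conc[, "TMx"],
                            length_weighted = FALSE, edges = NULL) {
  if (length(tmx) != n_cells(tissue)) stop("tmx must have one value per cell")
  if (any(!is.finite(tmx)) || any(tmx <= 0)) {
    stop("TMx concentrations must be positive and finite")
  }
  ed <- if (is.null(edges)) tissue_edges(tissue) else edges
  w1 <- tmx[ed$c1]
  w2 <- ifelse(is.na(ed$c2), -Inf, tmx[ed$c2])
  m <- pmax(w1, w2)

  inc_cell <- c(ed$c1, ed$c2[!is.na(ed$c2)])
  inc_m <- c(m, m[!is.na(ed$c2)])
  if (length_weighted) {
    len <- sqrt((tissue$xy[ed$v2, 1L] - tissue$xy[ed$v1, 1L])^2 +
                  (tissue$xy[ed$v2, 2L] - tissue$xy[ed$v1, 2L])^2)
    inc_w <- c(len, len[!is.na(ed$c2)])
    mean_m <- rowsum(inc_m * inc_w, inc_cell)[, 1L] /
      rowsum(inc_w, inc_cell)[, 1L]
  } else {
    mean_m <- rowsum(inc_m, inc_cell)[, 1L] / tabulate(inc_cell, n_cells(tissue))
  }
  ## rowsum orders groups by sort(unique(inc_cell)) = 1..n (every cell has edges)
  lambda1 <- m / mean_m[ed$c1]
  lambda2 <- ifelse(is.na(ed$c2), NA_real_, m / mean_m[ed$c2])
  lambda_bar <- ifelse(is.na(ed$c2), lambda1, (lambda1 + lambda2) / 2)
  out <- ed
  out$lambda1 <- lambda1
  out$lambda2 <- lambda2
  out$lambda_bar <- lambda_bar
  structure(out, tmx = tmx, class = c("tension_factors", "data.frame"))
}

#' Uniform (identity) tension factors
#' @param tissue a `tissue`.
#' @return A `tension_factors` object with all factors equal to one.
#' @export
unit_factors <- function(tissue) {
  compute_factors(tissue, rep(1, n_cells(tissue)))
}

#' @export
print.tension_factors <- function(x, ...) {
  cat(sprintf("<tension_factors> %d edges; lambda_bar range [%.3g, %.3g]\n",
              nrow(x), min(x$lambda_bar), max(x$lambda_bar)))
  invisible(x)
}

## Graph distance (in cell rows) of every cell from the A/P interface:
## row 1 = cells with at least one neighbor in the other compartment.
rows_from_boundary <- function(tissue) {
  ed <- tissue_edges(tissue)
  ie <- ed[!ed$margin, , drop = FALSE]
  n <- n_cells(tissue)
  comp <- tissue$compartment
  row <- rep(NA_integer_, n)
  frontier <- unique(c(ie$c1[comp[ie$c1] != comp[ie$c2]],
                       ie$c2[comp[ie$c1] != comp[ie$c2]]))
  if (!length(frontier)) return(row)
  adj <- vector("list", n)
  for (k in seq_len(nrow(ie))) {
    a <- ie$c1[k]; b <- ie$c2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  row[frontier] <- 1L
  cur <- frontier
  r <- 1L
  while (length(cur)) {
    nxt <- unique(unlist(adj[cur], use.names = FALSE))
    nxt <- nxt[is.na(row[nxt])]
    r <- r + 1L
    row[nxt] <- r
    cur <- nxt
  }
  row
}

#' Boundary-to-bulk effective tension ratio
#'
#' Mean effective line tension (coefficient times effective scaling factor)
#' over A/P-boundary edges, divided by the same mean over bulk edges
#' (internal edges whose two cells both lie at least `bulk_rows` cell rows
#' from the boundary, in either compartment).
#'
#' @param tissue a `tissue`.
#' @param factors a `tension_factors` object for this tissue.
#' @param params a [mech_params()] object.
#' @param bulk_rows minimum row distance from the interface for an edge to
#'   count as bulk (default 3).
#' @return The dimensionless tension ratio.
#' @export
boundary_tension_ratio <- function(tissue, factors, params = mech_params(),
                                   bulk_rows = 3L) {
  comp <- tissue$compartment
  internal <- !factors$margin
  bnd <- internal & comp[factors$c1] != ifelse(is.na(factors$c2), comp[factors$c1],
                                               comp[factors$c2])
  rows <- rows_from_boundary(tissue)
  bulk <- internal & !bnd &
    rows[factors$c1] >= bulk_rows &
    ifelse(is.na(factors$c2), FALSE, rows[factors$c2] >= bulk_rows)
  if (!any(bnd) || !any(bulk)) {
    stop("need at least one boundary edge and one bulk edge")
  }
  lb <- params$lambda_bar
  mean(lb * factors$lambda_bar[bnd]) / mean(lb * factors$lambda_bar[bulk])
}
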