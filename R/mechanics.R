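## Mechanical energy and quasi-static relaxation.

## Flat mesh encoding shared with the compiled kernels. With `trust`,
## freshly computed factors stand in for the edge table (they embed it),
## skipping a re-derivation; callers that cannot guarantee freshness get
## the full consistency check.
flatten_tissue <- function(tissue, factors = NULL, trust = FALSE) {
  if (trust && !is.null(factors)) {
    ed <- factors
    lam <- factors$lambda_bar
  } else {
    ed <- tissue_edges(tissue)
    if (is.null(factors)) {
      lam <- rep(1, nrow(ed))
    } else {
      if (nrow(factors) != nrow(ed) ||
          any(factors$v1 != ed$v1) || any(factors$v2 != ed$v2)) {
        stop("tension factors do not match the tissue's edge set; recompute them")
      }
      lam <- factors$lambda_bar
    }
  }
  list(
    edges = cbind(ed$v1, ed$v2) - 1L,
    margin = as.integer(ed$margin),
    lam = lam,
    cell_idx = unlist(tissue$cells, use.names = FALSE) - 1L,
    cell_ptr = c(0L, cumsum(lengths(tissue$cells))),
    ed = ed
  )
}

#' Normalized mechanical energy of a tissue
#'
#' Evaluates the dimensionless work function: line tension summed over
#' edges (each edge weighted by its effective TMx scaling factor), a
#' quadratic area-elasticity term per cell around the cell's current target
#' area, and quadratic perimeter elasticity per cell.
#'
#' @param tissue a `tissue`.
#' @param params a [mech_params()] object.
#' @param factors optional [compute_factors()] result; `NULL` means all
#'   factors are one (the unmodified base vertex model).
#' @return A list of class `energy_breakdown` with components `tension`,
#'   `area`, `perimeter` and `total`.
#' @export
tissue_energy <- function(tissue, params = mech_params(), factors = NULL) {
  fl <- flatten_tissue(tissue, factors)
  e <- vm_energy_cpp(tissue$xy, fl$cell_idx, fl$cell_ptr, fl$edges,
                     fl$margin, fl$lam, params$lambda_bar,
                     params$lambda_bar_margin, params$gamma_bar,
                     tissue$target_area)
  structure(as.list(e), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("tension %.6g + area %.6g + perimeter %.6g = %.6g\n",
              x$tension, x$area, x$perimeter, x$total))
  invisible(x)
}

#' Analytic energy gradient
#'
#' Gradient of [tissue_energy()] with respect to all vertex positions.
#'
#' @inheritParams tissue_energy
#' @return V x 2 matrix of partial derivatives.
#' @export
energy_gradient <- function(tissue, params = mech_params(), factors = NULL) {
  fl <- flatten_tissue(tissue, factors)
  vm_gradient_cpp(tissue$xy, fl$cell_idx, fl$cell_ptr, fl$edges, fl$margin,
                  fl$lam, params$lambda_bar, params$lambda_bar_margin,
                  params$gamma_bar, tissue$target_area)
}

#' Relax a tissue to a local energy minimum
#'
#' Minimizes the normalized energy quasi-statically (limited-memory BFGS
#' with backtracking line search) until the largest gradient component
#' falls below `tol`. Between minimization rounds,
#' internal edges shorter than `t1_threshold` undergo T1 neighbor
#' exchanges, which is how cells rearrange and sort; tension factors are
#' recomputed from the stored TMx field after every topology change.
#'
#' @param tissue a `tissue`.
#' @param params a [mech_params()] object.
#' @param factors optional `tension_factors`; `NULL` for the uncoupled
#'   base model.
#' @param tol convergence threshold on the maximum gradient component.
#' @param maxit iteration cap for the minimizer (per round).
#' @param t1 fire T1 transitions on sub-threshold edges between rounds?
#' @param t1_threshold edge length below which a T1 is triggered, in units
#'   of \eqn{\sqrt{A_0}}.
#' @param max_rounds cap on T1/minimization rounds.
#' @param free_vertices optional logical vector over vertices; when given,
#'   only these vertices move (local relaxation around a perturbation) and
#'   convergence is judged on them alone.
#' @param t2_threshold area below which a fully crushed cell (all edges
#'   collapsed, T1 no longer possible) is extruded from the sheet; 0
#'   disables the safeguard.
#' @param factors_fresh set by internal callers that computed `factors`
#'   for exactly this topology, skipping one consistency check.
#' @param on_fail `"error"` (default) to stop when the minimizer does not
#'   converge, with the last state attached to the condition; `"warn"` to
#'   return the last state with a warning.
#' @return The relaxed `tissue`; attributes `relax_info` (iterations, final
#'   gradient norm, energy) and `n_t1` (T1 count fired during the call).
#' @export
relax <- function(tissue, params = mech_params(), factors = NULL,
                  tol = 1e-6, maxit = 50000L, t1 = TRUE,
                  t1_threshold = 0.05, max_rounds = 50L,
                  free_vertices = NULL, t2_threshold = 0.02,
                  factors_fresh = FALSE,
                  on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  stopifnot(tol > 0)
  n_t1 <- 0L
  n_t2 <- 0L
  res <- NULL
  used <- 0L
  round_cap <- min(as.integer(maxit), 2000L)
  fired_pairs <- character(0)  # junctions already exchanged in this call:
                               # re-collapse means a stable fourfold vertex,
                               # not an infinite exchange loop
  fresh <- isTRUE(factors_fresh)  # fresh factors embed a valid edge table
  for (round in seq_len(max_rounds)) {
    budget <- min(round_cap, as.integer(maxit) - used)
    fl <- flatten_tissue(tissue, factors, trust = fresh)
    fresh <- !is.null(factors)  # validated (or rebuilt) once; topology
                                # events refresh factors before reuse
    fm <- if (is.null(free_vertices)) NULL else {
      as.integer(rep_len(free_vertices, nrow(tissue$xy)))
    }
    res <- vm_relax_cpp(tissue$xy, fl$cell_idx, fl$cell_ptr, fl$edges,
                        fl$margin, fl$lam, params$lambda_bar,
                        params$lambda_bar_margin, params$gamma_bar,
                        tissue$target_area, tol, budget, fm)
    used <- used + res$niter
    tissue$xy <- res$xy
    if (!t1) break
    ## fire T1 exchanges on sub-threshold internal edges between rounds
    ed <- fl$ed
    len <- sqrt((tissue$xy[ed$v2, 1L] - tissue$xy[ed$v1, 1L])^2 +
                  (tissue$xy[ed$v2, 2L] - tissue$xy[ed$v1, 2L])^2)
    short <- which(!ed$margin & len < t1_threshold)
    if (!is.null(free_vertices)) {
      short <- short[free_vertices[ed$v1[short]] & free_vertices[ed$v2[short]]]
    }
    fired <- FALSE
    for (k in short[order(len[short])]) {
      pair <- paste(ed$v1[k], ed$v2[k])
      if (pair %in% fired_pairs) next
      t2 <- suppressWarnings(
        t1_transition(tissue, ed$v1[k], ed$v2[k], 1.5 * t1_threshold))
      if (isTRUE(attr(t2, "did_t1"))) {
        tissue <- t2
        fired_pairs <- c(fired_pairs, pair)
        n_t1 <- n_t1 + 1L
        fired <- TRUE
        break  # topology changed; re-derive edges and factors
      }
    }
    if (!fired) {
      ## collapsed margin edges fuse into a single margin vertex
      shortm <- which(ed$margin & len < t1_threshold)
      if (!is.null(free_vertices)) {
        shortm <- shortm[free_vertices[ed$v1[shortm]] &
                           free_vertices[ed$v2[shortm]]]
      }
      for (k in shortm[order(len[shortm])]) {
        t2 <- suppressWarnings(merge_margin_edge(tissue, ed$v1[k], ed$v2[k]))
        if (isTRUE(attr(t2, "did_merge"))) {
          tissue <- t2
          fired <- TRUE
          break
        }
      }
    }
    if (!fired && t2_threshold > 0) {
      ## fully crushed cells whose junctions can no longer exchange are
      ## extruded (numerical safeguard; see the methods vignette)
      geo <- cell_geom_cpp(tissue$xy,
                           unlist(tissue$cells, use.names = FALSE) - 1L,
                           c(0L, cumsum(lengths(tissue$cells))))
      crushed <- which(geo$area < t2_threshold & geo$perimeter < 2)
      if (length(crushed)) {
        ## adjacent crushed cells must be extruded together (a rosette of
        ## collapsed quads cannot be removed one cell at a time)
        comp <- clone_components(tissue, crushed)
        for (cc in comp) {
          t2 <- t2_collapse(tissue, cc)
          if (isTRUE(attr(t2, "did_t2"))) {
            tissue <- t2
            fired <- TRUE
            n_t2 <- n_t2 + length(cc)
            if (!is.null(factors)) {
              ## the removed cells drop out of the TMx field as well
              factors <- compute_factors(tissue, attr(factors, "tmx")[-cc])
              fresh <- TRUE
            }
            break  # cell ids shifted; recompute everything
          }
        }
      }
    } else if (fired && !is.null(factors)) {
      factors <- compute_factors(tissue, attr(factors, "tmx"))
      fresh <- TRUE
    }
    ## continue only if topology changed or the minimizer ran out of budget
    ## while still making progress
    if (!fired && (res$converged || res$niter < budget || used >= maxit)) break
  }
  if (!res$converged && res$gmax > tol) {
    msg <- sprintf("relaxation did not converge: max gradient %.3g after %d iterations",
                   res$gmax, res$niter)
    if (on_fail == "error") {
      cond <- structure(class = c("wingvertex_relax_error", "error", "condition"),
                        list(message = msg, call = sys.call(),
                             tissue = tissue, gmax = res$gmax))
      stop(cond)
    }
    warning(msg)
  }
  structure(tissue,
            relax_info = list(niter = res$niter, gmax = res$gmax,
                              energy = res$energy, converged = res$converged),
            n_t1 = n_t1, n_t2 = n_t2)
}

#' Model line tension of one edge (laser-ablation proxy)
#'
#' Returns the effective line-tension coefficient
#' \eqn{\bar\Lambda \bar\lambda_{ij}} of an internal edge -- the model
#' force along the junction that a laser-ablation recoil experiment would
#' probe. Ratios of this quantity between boundary and bulk junctions are
#' comparable to experimentally measured recoil ratios.
#'
#' @param tissue a `tissue`.
#' @param params a [mech_params()] object.
#' @param factors a `tension_factors` object.
#' @param edge row index into [tissue_edges()] / `factors`.
#' @return The scalar effective tension of the edge.
#' @export
laser_ablation_proxy <- function(tissue, params, factors, edge) {
  if (edge < 1L || edge > nrow(factors)) stop("no such edge")
  if (factors$margin[edge]) stop("tension proxy is defined for internal edges only")
  params$lambda_bar * factors$lambda_bar[edge]
}
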