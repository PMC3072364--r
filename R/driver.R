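## Simulation driver: growth, clone seeding, and the coupled
## growth -> signaling -> tension -> relaxation cycle.

#' Simulation configuration
#'
#' Bundles every knob of a simulation run. The defaults are the standard
#' study conditions: 220 starting cells grown to 6000, 20 smo-mutant cells
#' paired with adjacent twin spots when clones are enabled, and 2 um per
#' cell diameter for converting model lengths to physical distances.
#'
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param n_start starting cell count (grid construction).
#' @param n_stop cell count at which the run stops.
#' @param clones enable smo-mutant / twin-spot clone seeding?
#' @param n_mutant number of mutant cells (each paired with one twin).
#' @param mech a [mech_params()] object.
#' @param kinetics a [kinetic_params()] object.
#' @param growth_steps number of target-area increments (each followed by a
#'   relaxation) over which a growing cell doubles its target area before
#'   dividing.
#' @param relax_tol gradient tolerance used for in-run relaxations.
#' @param relax_maxit minimizer iteration cap per relaxation.
#' @param signaling_tol quasi-steady-state tolerance per cycle.
#' @param signaling_tmax signaling integration-time cap per cycle.
#' @param t1_threshold T1 trigger length, units of \eqn{\sqrt{A_0}}.
#' @param snapshot_every record a snapshot every this many divisions
#'   (the final state is always recorded).
#' @param um_per_cell_diameter physical calibration of distances.
#' @param factors_enabled couple the TMx field into the energy? Disabling
#'   it (factors forced to one) is the negative control in which the
#'   boundary roughens through random divisions.
#' @param local_rows radius (in cell rows) of the patch relaxed after each
#'   growth increment; mechanical perturbations are screened over a few
#'   rows, so relaxing a local patch reproduces the global minimum to high
#'   accuracy at a fraction of the cost.
#' @param global_relax_every run a full (all-vertex) relaxation every this
#'   many divisions, and always at the end of a run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_start = 220L, n_stop = 6000L,
                       clones = FALSE, n_mutant = 20L,
                       mech = mech_params(), kinetics = kinetic_params(),
                       growth_steps = 4L, relax_tol = 1e-4,
                       relax_maxit = 10000L, signaling_tol = 2e-3,
                       signaling_tmax = 1500, t1_threshold = 0.05,
                       snapshot_every = 250L, um_per_cell_diameter = 2,
                       factors_enabled = TRUE, local_rows = 4L,
                       global_relax_every = 25L) {
  stopifnot(n_start >= 1L, n_stop >= n_start, relax_tol > 0,
            signaling_tol > 0, t1_threshold > 0, um_per_cell_diameter > 0,
            growth_steps >= 1L)
  if (clones && n_mutant > n_start / 4) {
    stop("n_mutant must not exceed a quarter of the starting cells")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d -> %d cells%s, coupling %s\n",
              x$seed, x$n_start, x$n_stop,
              if (x$clones) sprintf(", %d smo- clones + twins", x$n_mutant) else "",
              if (x$factors_enabled) "on" else "off"))
  invisible(x)
}

## cells within `k` adjacency steps of the seed cells
cells_within <- function(tissue, seeds, k, edges = NULL) {
  adj <- cell_adjacency(tissue, edges)
  seen <- logical(n_cells(tissue))
  seen[seeds] <- TRUE
  cur <- seeds
  for (i in seq_len(k)) {
    nxt <- unique(unlist(adj[cur], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    cur <- nxt
  }
  which(seen)
}

## cell adjacency list from internal edges
cell_adjacency <- function(tissue, edges = NULL) {
  ed <- if (is.null(edges)) tissue_edges(tissue) else edges
  ie <- ed[!ed$margin, , drop = FALSE]
  adj <- rep(list(integer(0)), n_cells(tissue))
  got <- split(c(ie$c2, ie$c1), c(ie$c1, ie$c2))
  adj[as.integer(names(got))] <- got
  adj
}

#' Seed smo-mutant clones with adjacent twin spots
#'
#' Relabels `n` background cells as smo mutants (zero Smo production) and,
#' for each, one adjacent background cell as its twin spot (doubled Smo
#' production), mimicking mitotic recombination. Pairs are drawn uniformly
#' over the tissue and kept non-adjacent to each other so each pair founds
#' a distinct clone lineage (distinct clone ids).
#'
#' @param tissue a `tissue` (all background genotype where seeding occurs).
#' @param n number of mutant/twin pairs.
#' @return The relabeled tissue.
#' @export
seed_clones <- function(tissue, n) {
  if (n == 0L) return(tissue)
  adj <- cell_adjacency(tissue)
  if (sum(tissue$genotype == GENO_BACKGROUND) < 2L * n) {
    stop("not enough unlabeled cells to seed ", n, " clone pairs")
  }
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("could not place ", n, " mutant/twin pairs with the required spacing")
    }
    free <- which(tissue$genotype == GENO_BACKGROUND)
    ## candidate mutant: background cell whose whole neighborhood is background
    c0 <- free[sample.int(length(free), 1L)]
    nb <- adj[[c0]]
    if (any(tissue$genotype[nb] != GENO_BACKGROUND)) next
    ok_twin <- nb[vapply(nb, function(b) {
      all(tissue$genotype[setdiff(adj[[b]], c0)] == GENO_BACKGROUND)
    }, logical(1))]
    if (!length(ok_twin)) next
    tw <- ok_twin[sample.int(length(ok_twin), 1L)]
    placed <- placed + 1L
    tissue$genotype[c0] <- GENO_SMO_MUTANT
    tissue$genotype[tw] <- GENO_TWIN_SPOT
    tissue$clone_id[c(c0, tw)] <- placed
  }
  tissue
}

## Current factors for a config (identity when coupling is disabled).
config_factors <- function(tissue, config) {
  if (config$factors_enabled) compute_factors(tissue) else NULL
}

#' One growth cycle
#'
#' Advances the simulation by one quasi-static cycle: (a) the currently
#' growing cell (the unique cell with target area above one; if none, a
#' cell chosen uniformly at random) increments its target area, dividing at
#' a uniformly random angle once it reaches twice the reference area;
#' (b) signaling is advanced to quasi-steady state; (c) tension factors are
#' recomputed from the TMx field; (d) the energy is relaxed (with T1
#' checks). The cell count increases by zero or one. On an internal error
#' the pre-call tissue is returned unchanged with attribute `cycle_error`.
#'
#' @param tissue a `tissue`.
#' @param config a [sim_config()].
#' @param local relax only a patch of `config$local_rows` cell rows around
#'   the growing cell (the driver interleaves periodic global relaxations)?
#' @return Updated tissue; attributes `divided` (logical) and `n_t1`.
#' @export
growth_cycle <- function(tissue, config, local = FALSE) {
  pre <- tissue
  out <- tryCatch({
    growing <- which(tissue$target_area > 1)
    if (!length(growing)) {
      growing <- sample.int(n_cells(tissue), 1L)
    } else {
      growing <- growing[[1L]]
    }
    tissue$target_area[growing] <- min(
      2, tissue$target_area[growing] + 1 / config$growth_steps)
    divided <- FALSE
    if (tissue$target_area[growing] >= 2 - 1e-9) {
      for (try in 1:25) {
        ang <- runif(1L, 0, pi)
        t2 <- tryCatch(divide_cell(tissue, growing, ang,
                                   eps = if (try <= 15L) 0.05 else 0.01),
                       wingvertex_retry = function(e) NULL)
        if (!is.null(t2)) { tissue <- t2; divided <- TRUE; break }
      }
      if (!divided) {
        ## a heavily squeezed cell may admit no valid division line at
        ## all (every chord would make a triangle); abandon this division
        ## and let growth move on to another cell
        warning("cell ", growing,
                " admits no valid division line; division abandoned")
        tissue$target_area[growing] <- 1
      }
    }
    ed <- tissue_edges(tissue)  # shared by signaling, factors and patching
    tissue <- advance_signaling(tissue, config$kinetics,
                                tol = config$signaling_tol,
                                t_max = config$signaling_tmax,
                                on_fail = "warn", edges = ed)
    factors <- if (config$factors_enabled) {
      compute_factors(tissue, edges = ed)
    }
    free <- NULL
    if (local) {
      ## the relaxed patch covers the growing cell plus every junction
      ## already below the T1 threshold, so pending rearrangements are not
      ## starved between the periodic global relaxations
      len <- sqrt((tissue$xy[ed$v2, 1L] - tissue$xy[ed$v1, 1L])^2 +
                    (tissue$xy[ed$v2, 2L] - tissue$xy[ed$v1, 2L])^2)
      nearby <- !ed$margin & len < config$t1_threshold
      seeds <- unique(c(growing, ed$c1[nearby], ed$c2[nearby]))
      patch <- cells_within(tissue, seeds, config$local_rows, edges = ed)
      free <- logical(nrow(tissue$xy))
      free[unlist(tissue$cells[patch], use.names = FALSE)] <- TRUE
    }
    tissue <- relax(tissue, config$mech, factors,
                    tol = config$relax_tol, maxit = config$relax_maxit,
                    t1_threshold = config$t1_threshold,
                    free_vertices = free, factors_fresh = TRUE,
                    on_fail = "warn")
    structure(tissue, divided = divided)
  }, error = function(e) {
    structure(pre, cycle_error = conditionMessage(e), divided = FALSE)
  })
  out
}

#' Run a full growth simulation
#'
#' Builds the initial grid, optionally seeds clones, equilibrates signaling
#' and mechanics, then iterates [growth_cycle()] until `n_stop` cells are
#' reached. Deterministic given `config$seed` (a single RNG stream drives
#' cell choice, division angles and clone placement).
#'
#' @param config a [sim_config()].
#' @param quiet suppress progress messages?
#' @return An object of class `disc_sim`: list with the final `tissue`,
#'   `snapshots` (list of tissues at the configured cadence), `metrics`
#'   (one row per division: cell count, energy terms, boundary roughness,
#'   T1 count) and the `config`.
#' @export
simulate_disc <- function(config = sim_config(), quiet = TRUE) {
  set.seed(config$seed)
  tissue <- build_initial_grid(config$n_start)
  if (config$clones) tissue <- seed_clones(tissue, config$n_mutant)
  ## initial equilibration: concentrations start at zero everywhere
  tissue <- advance_signaling(tissue, config$kinetics,
                              tol = config$signaling_tol,
                              t_max = 10 * config$signaling_tmax,
                              on_fail = "warn")
  tissue <- relax(tissue, config$mech, config_factors(tissue, config),
                  tol = config$relax_tol, maxit = config$relax_maxit,
                  t1_threshold = config$t1_threshold, on_fail = "warn")
  snapshots <- list()
  metrics <- list()
  divisions <- 0L
  cycles <- 0L
  record <- function(tissue) {
    e <- tissue_energy(tissue, config$mech, config_factors(tissue, config))
    data.frame(cycle = cycles, divisions = divisions,
               n_cells = n_cells(tissue),
               e_tension = e$tension, e_area = e$area,
               e_perimeter = e$perimeter, e_total = e$total,
               roughness = tryCatch(boundary_roughness(tissue),
                                    error = function(e) NA_real_))
  }
  metrics[[length(metrics) + 1L]] <- record(tissue)
  while (n_cells(tissue) < config$n_stop) {
    cycles <- cycles + 1L
    tissue <- growth_cycle(tissue, config, local = cycles > 1L)
    if (!is.null(attr(tissue, "cycle_error"))) {
      warning("cycle ", cycles, " failed: ", attr(tissue, "cycle_error"))
      break
    }
    if (isTRUE(attr(tissue, "divided"))) {
      divisions <- divisions + 1L
      if (divisions %% config$global_relax_every == 0L) {
        ## periodic full relaxation keeps long-range stresses equilibrated
        tissue <- relax(tissue, config$mech, config_factors(tissue, config),
                        tol = config$relax_tol, maxit = config$relax_maxit,
                        t1_threshold = config$t1_threshold, on_fail = "warn")
      }
      metrics[[length(metrics) + 1L]] <- record(tissue)
      if (divisions %% config$snapshot_every == 0L) {
        snapshots[[length(snapshots) + 1L]] <- tissue
      }
      if (!quiet && divisions %% 100L == 0L) {
        message(sprintf("division %d: %d cells", divisions, n_cells(tissue)))
      }
    }
  }
  ## final full relaxation
  tissue <- relax(tissue, config$mech, config_factors(tissue, config),
                  tol = config$relax_tol, maxit = config$relax_maxit,
                  t1_threshold = config$t1_threshold, on_fail = "warn")
  snapshots[[length(snapshots) + 1L]] <- tissue
  structure(list(tissue = tissue, snapshots = snapshots,
                 metrics = do.call(rbind, metrics), config = config),
            class = "disc_sim")
}

#' @export
print.disc_sim <- function(x, ...) {
  cat(sprintf("<disc_sim> seed %d: %d cells (%d snapshots, %d divisions)\n",
              x$config$seed, n_cells(x$tissue), length(x$snapshots),
              max(x$metrics$divisions)))
  invisible(x)
}

#' @export
summary.disc_sim <- function(object, ...) {
  print(object)
  m <- object$metrics
  cat(sprintf("final energy %.4g, boundary roughness %.3f\n",
              m$e_total[nrow(m)], m$roughness[nrow(m)]))
  summary(object$tissue)
  invisible(object)
}

#' @export
plot.disc_sim <- function(x, ...) {
  plot(x$tissue, fill = x$tissue$conc[, "TMx"], ...)
  invisible(x)
}
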