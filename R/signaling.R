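## Hedgehog pathway: finite-volume diffusion of Hh over the cell polygons
## and per-cell mass-action kinetics for the seven modeled species.
##
## Hh is produced posteriorly, diffuses from cell to cell (two-point
## finite-volume flux, zero flux at the tissue margin) and binds reversibly
## to its anterior receptor Ptc. Free Ptc actively pumps the hypothetical
## Smo ligand Lx away from Smo; Hh binding titrates free Ptc, letting Lx
## accumulate and form the active complex LxSmo, which drives anterior
## production of both Ptc (the classic Ptc stripe) and the tension effector
## TMx. All cells express TMx at a basal rate.

## internal edges with finite-volume weights l_ab / d_ab; the centroid
## distance is floored so transiently crushed cells (centroids almost
## coincident) cannot drive the transmissibility, and with it the explicit
## stability bound, to pathological values
fv_weights <- function(tissue, edges = NULL) {
  ed <- if (is.null(edges)) tissue_edges(tissue) else edges
  ie <- ed[!ed$margin, , drop = FALSE]
  len <- sqrt((tissue$xy[ie$v2, 1L] - tissue$xy[ie$v1, 1L])^2 +
                (tissue$xy[ie$v2, 2L] - tissue$xy[ie$v1, 2L])^2)
  ctr <- cell_centroids(tissue)
  d <- sqrt(rowSums((ctr[ie$c1, , drop = FALSE] - ctr[ie$c2, , drop = FALSE])^2))
  list(c1 = ie$c1, c2 = ie$c2, w = len / pmax(d, 0.1))
}

#' One explicit finite-volume diffusion step for Hh
#'
#' Updates only the Hh column: each cell exchanges Hh with its neighbors
#' at rate \eqn{D\, l_{\alpha\beta}/d_{\alpha\beta}} per unit concentration
#' difference (shared edge length over centroid distance), scaled by the
#' cell area; margin edges carry no flux, so total Hh amount
#' (concentration times area) is conserved exactly.
#'
#' @param tissue a `tissue`.
#' @param D diffusion coefficient.
#' @param dt time step; must satisfy the explicit stability bound
#'   \eqn{dt \le \min_\alpha A_\alpha / \sum_\beta D l/d}.
#' @return The tissue with updated Hh concentrations.
#' @export
diffusion_step <- function(tissue, D, dt) {
  fw <- fv_weights(tissue)
  areas <- cell_areas(tissue)
  wsum <- rowsum(c(D * fw$w, D * fw$w), c(fw$c1, fw$c2))[, 1L]
  idx <- as.integer(rownames(rowsum(c(D * fw$w, D * fw$w), c(fw$c1, fw$c2))))
  bound <- min(areas[idx] / wsum)
  if (dt > bound) {
    stop(sprintf("dt = %g violates the explicit stability bound dt <= %g",
                 dt, bound))
  }
  hh <- tissue$conc[, "Hh"]
  q <- D * fw$w * (hh[fw$c2] - hh[fw$c1])
  flux <- rep(0, n_cells(tissue))
  acc <- rowsum(c(q, -q), c(fw$c1, fw$c2))
  flux[as.integer(rownames(acc))] <- acc[, 1L]
  tissue$conc[, "Hh"] <- hh + dt * flux / areas
  tissue
}

## R-side mass-action right-hand side (reference implementation; the
## compiled core carries its own copy for the inner loop). `state` is a
## matrix with the 7 species columns; isA/g are per-row.
kinetics_rhs <- function(state, isA, g, p) {
  Hh <- state[, 1L]; Ptc <- state[, 2L]; HhPtc <- state[, 3L]
  Smo <- state[, 4L]; Lx <- state[, 5L]; LxSmo <- state[, 6L]
  TMx <- state[, 7L]
  bind <- p[["k_on"]] * Hh * Ptc - p[["k_off"]] * HhPtc
  assoc <- p[["k_f"]] * Lx * Smo - p[["k_r"]] * LxSmo
  cbind(
    ifelse(isA, 0, p[["rho_Hh_P"]]) - bind - p[["delta_Hh"]] * Hh,
    ifelse(isA, p[["rho_Ptc_basal_A"]] + p[["k_Ptc_Smo_A"]] * LxSmo, 0) -
      bind - p[["delta_Ptc"]] * Ptc,
    bind - p[["delta_HhPtc"]] * HhPtc,
    p[["rho_Smo"]] * g - assoc - p[["delta_Smo"]] * Smo,
    p[["rho_Lx"]] - assoc - p[["k_pump"]] * Ptc * Lx - p[["delta_Lx"]] * Lx,
    assoc - p[["delta_LxSmo"]] * LxSmo,
    p[["rho_TMx_basal"]] + ifelse(isA, p[["k_TMx_Smo_A"]] * LxSmo, 0) -
      p[["delta_TMx"]] * TMx
  )
}

#' Advance the non-diffusive kinetics of one or more cells
#'
#' Integrates the mass-action reaction terms (everything except Hh
#' diffusion) with a classical fourth-order Runge-Kutta step. If the step
#' would drive any concentration negative it is retried with four
#' substeps; a persistent violation is an error.
#'
#' @param state named numeric vector of the 7 species, or a matrix with one
#'   row per cell (columns in `SPECIES` order).
#' @param label list with `compartment` (`"anterior"`/`"posterior"`) and
#'   `genotype` (`"background"`, `"smo_mutant"`, `"twin_spot"`); vectors
#'   are recycled over rows.
#' @param params a [kinetic_params()] object.
#' @param dt time step (> 0).
#' @return Updated state, same shape as the input.
#' @export
kinetics_step <- function(state, label, params, dt) {
  stopifnot(dt > 0)
  vec <- is.null(dim(state))
  m <- if (vec) matrix(state, 1L) else as.matrix(state)
  comp <- label$compartment
  geno <- label$genotype
  if (is.character(comp)) comp <- match(comp, comp_names)
  if (is.character(geno)) geno <- match(geno, geno_names) - 1L
  isA <- rep_len(comp == COMP_A, nrow(m))
  g <- rep_len(c(1, 0, 2)[geno + 1L], nrow(m))
  rk4 <- function(m, dt) {
    k1 <- kinetics_rhs(m, isA, g, params)
    k2 <- kinetics_rhs(m + dt / 2 * k1, isA, g, params)
    k3 <- kinetics_rhs(m + dt / 2 * k2, isA, g, params)
    k4 <- kinetics_rhs(m + dt * k3, isA, g, params)
    m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- rk4(m, dt)
  if (any(out < 0)) {
    out <- m
    for (i in 1:4) out <- rk4(out, dt / 4)
    if (any(out < -1e-8)) stop("negative concentration after step-size reduction")
    out[out < 0] <- 0
  }
  if (vec) setNames(drop(out), SPECIES) else {
    colnames(out) <- SPECIES
    out
  }
}

#' Advance the coupled signaling system to quasi-steady state
#'
#' Operator-split (Strang) integration on a fixed mesh: implicit
#' finite-volume diffusion of Hh (backward Euler, conjugate-gradient
#' solve) around an L-stable second-order implicit kinetics step per cell,
#' until the maximum relative concentration change per unit time falls
#' below `tol`.
#'
#' @param tissue a `tissue`.
#' @param params a [kinetic_params()] object.
#' @param tol relative-rate convergence threshold.
#' @param t_max integration-time cap.
#' @param check_every macro steps between convergence checks.
#' @param dt_macro operator-splitting macro step (all sub-integrators are
#'   implicit and unconditionally stable).
#' @param on_fail `"error"` to stop when `t_max` is reached before
#'   convergence (with the residual in the message), `"warn"` to continue.
#' @return The tissue with updated concentrations; attribute
#'   `signal_info` holds integration time, residual and convergence flag.
#' @export
advance_signaling <- function(tissue, params = kinetic_params(), tol = 1e-4,
                              t_max = 2000, check_every = 8L,
                              dt_macro = 0.25,
                              on_fail = c("error", "warn"), edges = NULL) {
  on_fail <- match.arg(on_fail)
  fw <- fv_weights(tissue, edges)
  res <- signal_advance_cpp(tissue$conc, tissue$compartment, tissue$genotype,
                            cell_areas(tissue),
                            cbind(fw$c1, fw$c2) - 1L, fw$w,
                            as.numeric(params), tol, t_max,
                            as.integer(check_every), dt_macro)
  if (!res$converged) {
    msg <- sprintf("signaling did not reach steady state: residual %.3g after t = %g",
                   res$max_rate, res$t)
    if (on_fail == "error") stop(msg) else warning(msg)
  }
  colnames(res$conc) <- SPECIES
  tissue$conc <- res$conc
  structure(tissue, signal_info = list(t = res$t, residual = res$max_rate,
                                       converged = res$converged))
}

#' Steady-state concentration profile on a fixed mesh
#'
#' Runs [advance_signaling()] to convergence on a non-growing tissue and
#' returns the per-cell concentration table together with a projection of
#' every species onto the anteroposterior axis (x relative to the A/P
#' interface).
#'
#' @param strip a `tissue` (typically a [hex_strip()] fixture).
#' @param params a [kinetic_params()] object.
#' @param tol relative-rate convergence threshold.
#' @param t_max integration-time cap.
#' @return List with `tissue` (converged state), `cells` (data frame:
#'   cell id, centroid, compartment, row distance from the interface, and
#'   the 7 species plus total Ptc `Ptc_T = Ptc + HhPtc`), and `profile`
#'   (long-format projection: `x`, `species`, `value`).
#' @export
steady_profile <- function(strip, params = kinetic_params(), tol = 1e-4,
                           t_max = 5000) {
  strip <- advance_signaling(strip, params, tol = tol, t_max = t_max)
  ctr <- cell_centroids(strip)
  x0 <- ap_interface_x(strip)
  cells <- data.frame(
    cell = seq_len(n_cells(strip)),
    x = ctr[, 1L] - x0, y = ctr[, 2L],
    compartment = comp_names[strip$compartment],
    row = rows_from_boundary(strip),
    strip$conc,
    Ptc_T = strip$conc[, "Ptc"] + strip$conc[, "HhPtc"]
  )
  long <- do.call(rbind, lapply(c(SPECIES, "Ptc_T"), function(s) {
    data.frame(x = cells$x, species = s, value = cells[[s]])
  }))
  list(tissue = strip, cells = cells, profile = long)
}

## x position of the A/P interface: mean midpoint of boundary edges.
ap_interface_x <- function(tissue) {
  ed <- tissue_edges(tissue)
  comp <- tissue$compartment
  b <- !ed$margin & comp[ed$c1] != comp[ifelse(is.na(ed$c2), ed$c1, ed$c2)]
  if (!any(b)) return(NA_real_)
  mean((tissue$xy[ed$v1[b], 1L] + tissue$xy[ed$v2[b], 1L]) / 2)
}

#' Calibrate the TMx induction rate to a target boundary ratio
#'
#' TMx is purely downstream of the pathway: its steady level in an anterior
#' cell is \eqn{(\rho_{TMx} + k\,[LxSmo])/\delta_{TMx}} and basal level is
#' \eqn{\rho_{TMx}/\delta_{TMx}}. Given the steady active-Smo level of the
#' first anterior row on a reference strip, the induction coefficient
#' `k_TMx_Smo_A` that yields a prescribed A1/basal TMx ratio therefore
#' follows in closed form; this routine solves for it and verifies the
#' result by a second steady-state run.
#'
#' @param params starting [kinetic_params()].
#' @param target_ratio desired A1-to-basal TMx ratio (default 12).
#' @param strip reference tissue (default a 20 x 20 hexagonal strip).
#' @param tol steady-state tolerance.
#' @return Updated `kinetic_params`, with attribute `achieved_ratio`.
#' @export
calibrate_tmx <- function(params = kinetic_params(), target_ratio = 12,
                          strip = hex_strip(20, 20), tol = 1e-5) {
  prof <- steady_profile(strip, params, tol = tol)
  cells <- prof$cells
  a1 <- cells$compartment == "anterior" & cells$row == 1L
  lxsmo_a1 <- mean(cells$LxSmo[a1])
  if (lxsmo_a1 <= 0) stop("no active Smo in the first anterior row; cannot calibrate")
  k <- (target_ratio - 1) * params[["rho_TMx_basal"]] / lxsmo_a1
  out <- params
  out[["k_TMx_Smo_A"]] <- k
  chk <- steady_profile(strip, out, tol = tol)
  basal <- mean(chk$cells$TMx[chk$cells$compartment == "posterior"])
  a1_tmx <- mean(chk$cells$TMx[chk$cells$compartment == "anterior" &
                                 chk$cells$row == 1L])
  structure(out, achieved_ratio = a1_tmx / basal)
}
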