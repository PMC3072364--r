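## Parameter containers for mechanics and signaling kinetics.

#' Mechanical parameters of the normalized vertex-model energy
#'
#' The energy is written in dimensionless form: lengths in units of
#' \eqn{\sqrt{A_0}}, areas in units of \eqn{A_0}, so the area-elasticity
#' coefficient is absorbed and two coefficients remain: the line tension
#' \eqn{\bar\Lambda} and the perimeter elasticity \eqn{\bar\Gamma}. Margin
#' edges (tissue boundary) may carry their own line-tension coefficient.
#' The defaults are the standard parameter point of the underlying vertex
#' model (`lambda_bar = 0.12`, `gamma_bar = 0.04`), at which relaxed bulk
#' tissue reproduces the observed polygon-class statistics.
#'
#' @param lambda_bar dimensionless line-tension coefficient.
#' @param gamma_bar dimensionless perimeter-elasticity coefficient (>= 0).
#' @param lambda_bar_margin line tension applied to margin edges.
#' @param target_area cell target area (1 in normalized units; corresponds
#'   to a regular hexagon of edge length `sqrt(2/(3*sqrt(3)))`).
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(lambda_bar = 0.12, gamma_bar = 0.04,
                        lambda_bar_margin = lambda_bar, target_area = 1) {
  stopifnot(gamma_bar >= 0, target_area > 0, is.finite(lambda_bar_margin))
  structure(list(lambda_bar = lambda_bar, gamma_bar = gamma_bar,
                 lambda_bar_margin = lambda_bar_margin,
                 target_area = target_area),
            class = "mech_params")
}

## Fixed parameter order shared with the compiled signaling core.
KINETIC_ORDER <- c(
  "D", "rho_Hh_P", "k_on", "k_off", "rho_Ptc_basal_A", "k_Ptc_Smo_A",
  "rho_Smo", "rho_Lx", "k_pump", "k_f", "k_r", "rho_TMx_basal",
  "k_TMx_Smo_A",
  "delta_Hh", "delta_Ptc", "delta_HhPtc", "delta_Smo", "delta_Lx",
  "delta_LxSmo", "delta_TMx"
)

#' Kinetic parameters of the Hedgehog pathway model
#'
#' Rates are in arbitrary concentration units per unit signaling time; the
#' diffusion coefficient `D` is in units of cell area per unit time. The
#' shipped defaults were produced by [calibrate_tmx()] (see the methods
#' vignette): they yield a sigmoid total-Ptc stripe anterior to the
#' boundary, a graded anterior TMx stripe at least ten cells wide, a basal
#' TMx level `rho_TMx_basal / delta_TMx = 0.2` a.u. everywhere, and a
#' first-anterior-row TMx level of about 2.4 a.u. (twelve-fold above basal).
#'
#' @param D Hh diffusion coefficient.
#' @param rho_Hh_P Hh production rate (posterior cells only).
#' @param k_on,k_off Hh--Ptc binding and unbinding rates.
#' @param rho_Ptc_basal_A basal Ptc production (anterior only).
#' @param k_Ptc_Smo_A Ptc production per unit active Smo (anterior only).
#' @param rho_Smo Smo production rate (all cells; multiplied by the genotype
#'   factor: 0 in smo mutants, 2 in twin spots).
#' @param rho_Lx passive Lx influx from its reservoir.
#' @param k_pump Lx removal rate per unit free (unbound) Ptc.
#' @param k_f,k_r Lx--Smo association and dissociation rates.
#' @param rho_TMx_basal basal TMx production (all cells).
#' @param k_TMx_Smo_A TMx production per unit active Smo (anterior only;
#'   the knob varied to set the boundary TMx ratio).
#' @param delta_Hh,delta_Ptc,delta_HhPtc,delta_Smo,delta_Lx,delta_LxSmo,delta_TMx
#'   first-order decay rates.
#' @return An object of class `kinetic_params` (a named numeric vector).
#' @export
kinetic_params <- function(D = 1.6,
                           rho_Hh_P = 0.5,
                           k_on = 4.0,
                           k_off = 0.005,
                           rho_Ptc_basal_A = 0.05,
                           k_Ptc_Smo_A = 0.2,
                           rho_Smo = 0.1,
                           rho_Lx = 0.2,
                           k_pump = 20,
                           k_f = 0.1,
                           k_r = 0.1,
                           rho_TMx_basal = 0.02,
                           k_TMx_Smo_A = 1.274772,
                           delta_Hh = 0.15,
                           delta_Ptc = 0.1,
                           delta_HhPtc = 0.025,
                           delta_Smo = 0.1,
                           delta_Lx = 0.02,
                           delta_LxSmo = 0.1,
                           delta_TMx = 0.1) {
  p <- c(D = D, rho_Hh_P = rho_Hh_P, k_on = k_on, k_off = k_off,
         rho_Ptc_basal_A = rho_Ptc_basal_A, k_Ptc_Smo_A = k_Ptc_Smo_A,
         rho_Smo = rho_Smo, rho_Lx = rho_Lx, k_pump = k_pump, k_f = k_f,
         k_r = k_r, rho_TMx_basal = rho_TMx_basal,
         k_TMx_Smo_A = k_TMx_Smo_A, delta_Hh = delta_Hh,
         delta_Ptc = delta_Ptc, delta_HhPtc = delta_HhPtc,
         delta_Smo = delta_Smo, delta_Lx = delta_Lx,
         delta_LxSmo = delta_LxSmo, delta_TMx = delta_TMx)
  p <- p[KINETIC_ORDER]
  if (any(p < 0) || any(!is.finite(p))) stop("kinetic rates must be finite and >= 0")
  if (p[["D"]] <= 0) stop("D must be > 0")
  structure(p, class = "kinetic_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    "<mech_params> lambda_bar = %g, gamma_bar = %g, margin lambda = %g, A0 = %g\n",
    x$lambda_bar, x$gamma_bar, x$lambda_bar_margin, x$target_area))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  print(unclass(x))
  invisible(x)
}
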