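## Prescribed TMx profiles for fixed-mesh fixtures.

#' Impose a calibrated-shape TMx step profile on a tissue
#'
#' Writes an analytic TMx field into the tissue: the posterior compartment
#' sits at the basal level, and the anterior compartment carries a graded
#' stripe decaying exponentially with row distance from the interface, with
#' the first anterior row (A1) at `a1`. This is the prescribed-profile
#' counterpart of the field the signaling module produces at steady state,
#' useful for isolating the tension-coupling and mechanics modules.
#'
#' @param tissue a `tissue`.
#' @param basal basal TMx concentration (a.u.).
#' @param a1 first-anterior-row TMx concentration (default twelve-fold
#'   basal).
#' @param decay_cells e-folding length of the anterior stripe, in cell
#'   rows.
#' @return The tissue with its TMx column replaced.
#' @export
tmx_step_profile <- function(tissue, basal = 0.2, a1 = 12 * basal,
                             decay_cells = 4) {
  rows <- rows_from_boundary(tissue)
  tmx <- rep(basal, n_cells(tissue))
  ant <- tissue$compartment == COMP_A
  tmx[ant] <- basal + (a1 - basal) * exp(-(rows[ant] - 1) / decay_cells)
  tissue$conc[, "TMx"] <- tmx
  tissue
}
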