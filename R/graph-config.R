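#' Configuration for molecular graph perception
#'
#' Distance thresholds are expressed as a per-bond-class fraction of the sum
#' of van der Waals radii; covalent classes use tighter fractions than
#' metal-ligand contacts. Pairs well inside the threshold are accepted
#' outright; the rest undergo geometric validation (acute-angle and
#' ring-diagonal checks). For transition-state geometries a second pass
#' uniformly extends all distance criteria by `ts_scale` so elongated
#' (partially formed/broken) bonds are still perceived.
#'
#' @param factor_hx Threshold fraction for H-X pairs (either atom hydrogen,
#'   no metal involved).
#' @param factor_nonmetal Threshold fraction for nonmetal-nonmetal pairs.
#' @param factor_metal_ligand Threshold fraction for metal-nonmetal pairs.
#' @param factor_metal_metal Threshold fraction for metal-metal pairs.
#' @param direct_accept Fraction of the threshold below which a pair is
#'   accepted without geometric validation.
#' @param angle_min_metal,angle_min_nonmetal Minimum angle (degrees) a
#'   candidate bond may make with an existing bond at a metal / nonmetal
#'   endpoint.
#' @param ring_ratio_limit A candidate closing a 3-ring (or a chord across an
#'   existing 4-ring) is rejected when its length exceeds this multiple of
#'   the mean of the ring's existing bond lengths.
#' @param ts_scale Global threshold multiplier for the transition-state pass.
#' @param beam_width Number of candidate bond-order patterns kept during
#'   valence-charge optimization.
#' @param max_iter Iteration cap for the bond-order optimization.
#' @param w_valence,w_charge Penalty weights for valence deviation and
#'   absolute formal charge (`w_valence > w_charge`: valence dominates).
#' @param aromatic_planarity Maximum out-of-plane deviation (Angstrom) for a
#'   ring to count as an aromatic candidate.
#' @return A list of class `graph_config`.
#' @export
graph_config <- function(factor_hx = 0.42,
                         factor_nonmetal = 0.52,
                         factor_metal_ligand = 0.65,
                         factor_metal_metal = 0.70,
                         direct_accept = 0.6,
                         angle_min_metal = 15,
                         angle_min_nonmetal = 30,
                         ring_ratio_limit = 1.2,
                         ts_scale = 1.4,
                         beam_width = 8L,
                         max_iter = 200L,
                         w_valence = 4,
                         w_charge = 1,
                         aromatic_planarity = 0.15) {
  factors <- c(factor_hx, factor_nonmetal, factor_metal_ligand,
               factor_metal_metal)
  stopifnot(all(factors >= 0.38), all(factors <= 0.7),
            direct_accept > 0, direct_accept < 1,
            ts_scale >= 1, beam_width >= 1, w_valence > w_charge)
  structure(list(
    factor_hx = factor_hx,
    factor_nonmetal = factor_nonmetal,
    factor_metal_ligand = factor_metal_ligand,
    factor_metal_metal = factor_metal_metal,
    direct_accept = direct_accept,
    angle_min_metal = angle_min_metal,
    angle_min_nonmetal = angle_min_nonmetal,
    ring_ratio_limit = ring_ratio_limit,
    ts_scale = ts_scale,
    beam_width = as.integer(beam_width),
    max_iter = as.integer(max_iter),
    w_valence = w_valence,
    w_charge = w_charge,
    aromatic_planarity = aromatic_planarity), class = "graph_config")
}
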