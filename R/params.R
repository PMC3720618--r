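#' Gas constant in kcal mol-1 K-1
#'
#' @keywords internal
GAS_CONSTANT_KCAL <- 1.987204e-3

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT(298.15)
#' @export
kT <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KCAL * temperature
}

#' Hydrogen-bond scoring parameters
#'
#' Parameters of the 12-10 hydrogen-bond potential and of occupancy
#' book-keeping. The defaults are the published PPO values: equilibrium
#' donor-acceptor distance 1.8 A, well depth 8.4 kcal/mol, a 3.5 A
#' donor-acceptor occupancy cutoff and a 70% occupancy reporting threshold.
#'
#' @param r_eqm Equilibrium donor-acceptor distance (A), > 0.
#' @param epsilon Well depth (kcal/mol), > 0. The potential minimum is
#'   `-epsilon` at `r = r_eqm`.
#' @param occupancy_cutoff Distance (A) below which a snapshot counts as
#'   hydrogen-bonded; must exceed `r_eqm`.
#' @param report_threshold Occupancy fraction above which a bond contributes
#'   to the total hydrogen-bond energy.
#' @return A list of class `hbond_params`.
#' @examples
#' hbond_params()
#' @export
hbond_params <- function(r_eqm = 1.8, epsilon = 8.4,
                         occupancy_cutoff = 3.5, report_threshold = 0.70) {
  stopifnot(r_eqm > 0, epsilon > 0, occupancy_cutoff > r_eqm,
            report_threshold >= 0, report_threshold <= 1)
  structure(
    list(r_eqm = r_eqm, epsilon = epsilon,
         occupancy_cutoff = occupancy_cutoff,
         report_threshold = report_threshold),
    class = "hbond_params"
  )
}

#' Conformer triage configuration
#'
#' Settings for the multi-criteria selection of docked macrocycle conformers:
#' sizes of the docking-score and MM/PBSA shortlists, the strict upper bound
#' on the conformational energy penalty, the maximum reaction distance
#' (substrate meso methylene carbon to FAD N5) compatible with a productive
#' orientation, and the score used for final ranking.
#'
#' The penalty gate is strict (`penalty < penalty_max`); bioactive macrocycle
#' conformations are expected to pay less than 6 kcal/mol of deformation
#' energy. The 4.5 A orientation default is a package choice (the source
#' criterion is qualitative); it is deliberately configurable.
#'
#' @param k_docking,k_mmpbsa Shortlist sizes (most negative scores kept).
#' @param penalty_max Strict upper bound on the conformational penalty
#'   (kcal/mol).
#' @param orientation_max Maximum reaction distance (A), inclusive.
#' @param rank_by Score used to order the final candidates; MM/PBSA by
#'   default since it weighs ensemble energetics over a single docked pose.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(k_docking = 6L, k_mmpbsa = 6L,
                             penalty_max = 6.0, orientation_max = 4.5,
                             rank_by = c("mmpbsa", "docking")) {
  rank_by <- match.arg(rank_by)
  stopifnot(k_docking >= 1, k_mmpbsa >= 1, penalty_max > 0, orientation_max > 0)
  structure(
    list(k_docking = as.integer(k_docking), k_mmpbsa = as.integer(k_mmpbsa),
         penalty_max = penalty_max, orientation_max = orientation_max,
         rank_by = rank_by),
    class = "selection_config"
  )
}

#' Thermodynamic configuration
#'
#' Temperature, gas constant and standard concentration used whenever a
#' Michaelis constant is turned into a free energy. 298.15 K is assumed
#' throughout; published mutational free-energy shifts are consistent with
#' any temperature between 298 and 300 K, so the choice is configurable.
#'
#' @param temperature Kelvin.
#' @param gas_constant kcal mol-1 K-1.
#' @param standard_concentration Standard state, in molar.
#' @return A list of class `thermo_config`.
#' @export
thermo_config <- function(temperature = 298.15,
                          gas_constant = GAS_CONSTANT_KCAL,
                          standard_concentration = 1) {
  stopifnot(temperature > 0, gas_constant > 0, standard_concentration > 0)
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         standard_concentration = standard_concentration),
    class = "thermo_config"
  )
}

#' Rate constants of the product feedback inhibition scheme
#'
#' Elementary rate constants for the collapsed catalytic scheme
#' \deqn{E + S \rightleftharpoons ES \rightarrow EP \rightarrow E + P}
#' with a dead-end inhibitory complex
#' \deqn{E + P \rightleftharpoons EP^{inh}}
#' plus an uncatalyzed background oxidation \eqn{S \rightarrow P}. The
#' six-electron oxidation chemistry is collapsed into the single effective
#' `k_cat` step. Feedback inhibition is slow and tight: free enzyme
#' re-binds accumulated product slowly (`k_on_p` well below `k_on_s`) but
#' the resulting complex dissociates very slowly (`k_off_p` near zero), so
#' sequestration builds over tens of minutes and is effectively one-way on
#' the assay timescale.
#'
#' The defaults reproduce the qualitative enzyme-titration phenotype at
#' assay-scale concentrations (substrate a few tenths of a micromolar,
#' enzyme in the nanomolar range): curves at low enzyme stall below full
#' conversion with a clear velocity break, while high enzyme finishes
#' within about half an hour before sequestration can catch up. Only
#' `k_cat` (wild-type human PPO, 3 min-1) is an experimentally measured
#' number; the rest are phenomenological.
#'
#' @param k_on_s Substrate association, uM-1 min-1.
#' @param k_off_s Substrate dissociation, min-1.
#' @param k_cat Effective chemistry ES -> EP, min-1.
#' @param k_rel Product release EP -> E + P, min-1.
#' @param k_on_p Product re-association E + P -> EPinh (slow), uM-1 min-1.
#' @param k_off_p Dissociation of the dead-end product complex (tight),
#'   min-1.
#' @param k_auto Uncatalyzed auto-oxidation S -> P, min-1.
#' @return A list of class `rate_params`.
#' @export
rate_params <- function(k_on_s = 100, k_off_s = 50, k_cat = 3,
                        k_rel = 3, k_on_p = 0.5, k_off_p = 0.005,
                        k_auto = 0.005) {
  p <- list(k_on_s = k_on_s, k_off_s = k_off_s, k_cat = k_cat,
            k_rel = k_rel, k_on_p = k_on_p, k_off_p = k_off_p,
            k_auto = k_auto)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && x >= 0,
                          logical(1))]
  if (length(bad)) {
    abort(paste0("rate constants must be single non-negative numbers; bad: ",
                 paste(bad, collapse = ", ")))
  }
  structure(p, class = "rate_params")
}
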