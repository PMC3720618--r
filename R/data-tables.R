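ppo_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ppobind")
  if (path == "") {
    # source-tree fallback so the loaders work under devtools::load_all()
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("packaged table not found: ", file))
  path
}

#' Packaged kinetic constants of wild-type and mutant human PPO
#'
#' Michaelis constants and turnover numbers of wild-type human PPO and ten
#' binding-pocket mutants, as published, with their reported uncertainties
#' and the printed catalytic efficiencies. Units: `km_uM` in uM, `kcat_min`
#' in min-1, efficiency in uM-1 min-1.
#'
#' @return Tibble: `mutant`, `km_uM`, `km_err`, `kcat_min`, `kcat_err`,
#'   `kcat_per_km_printed`.
#' @examples
#' k <- ppo_hppo_kinetics()
#' dplyr::mutate(k, eff = catalytic_efficiency(kcat_min, km_uM))
#' @export
ppo_hppo_kinetics <- function() {
  readr::read_csv(ppo_extdata("hppo_kinetics.csv"), show_col_types = FALSE)
}

#' Packaged mutational free-energy shift components
#'
#' Enthalpic (`ddh`) and entropic (`minus_t_dds`, i.e. -T ddS) components
#' of the calculated binding free-energy shift for each tobacco (`mtppo`)
#' and human (`hppo`) PPO mutant, from a computational mutation scan, plus
#' the printed calculated and experimental totals for cross-checking. All
#' values kcal/mol.
#'
#' @return Tibble: `set`, `mutant`, `ddh`, `minus_t_dds`,
#'   `ddg_calc_printed`, `ddg_expt_printed`.
#' @export
ppo_ddg_components <- function() {
  readr::read_csv(ppo_extdata("ddg_components.csv"), show_col_types = FALSE)
}

#' Packaged Michaelis constants of tobacco mitochondrial PPO
#'
#' Wild-type and mutant Km values (uM) for protoporphyrinogen IX.
#'
#' @return Tibble: `mutant`, `km_uM`.
#' @export
ppo_tobacco_km <- function() {
  readr::read_csv(ppo_extdata("tobacco_km.csv"), show_col_types = FALSE)
}

#' Demonstration conformer table (partly synthetic)
#'
#' An 18-conformer score table for the macrocycle triage worked example.
#' The docking scores of the six docking-shortlisted conformers and the
#' MM/PBSA energies of the six MM/PBSA-shortlisted conformers are the
#' published values; all remaining scores, and every conformational penalty
#' and reaction distance, are synthetic stand-ins chosen to reproduce the
#' published gate outcomes (only M14 and M15 pay less than 6 kcal/mol of
#' conformational penalty and sit within reaction range of the FAD N5).
#'
#' @return Conformer tibble (`id`, `docking_score`, `mmpbsa_energy`,
#'   `penalty`, `reaction_distance`).
#' @examples
#' suppressMessages(select_conformers(ppo_conformer_demo()))$id
#' @export
ppo_conformer_demo <- function() {
  validate_conformers(
    readr::read_csv(ppo_extdata("conformers_synthetic.csv"),
                    show_col_types = FALSE))
}
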