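#' Validate a conformer record table
#'
#' @param records Data frame with columns `id`, `docking_score`,
#'   `mmpbsa_energy`, `penalty`, `reaction_distance`.
#' @return Validated tibble.
#' @keywords internal
validate_conformers <- function(records) {
  records <- as_tibble(records)
  need <- c("id", "docking_score", "mmpbsa_energy", "penalty",
            "reaction_distance")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("conformer table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate conformer id(s): ",
                 paste(unique(records$id[duplicated(records$id)]),
                       collapse = ", ")))
  }
  if (any(records$reaction_distance <= 0)) {
    abort("reaction_distance must be strictly positive")
  }
  if (any(records$penalty < 0)) abort("penalty must be non-negative")
  records
}

#' Shortlist conformers by a single score
#'
#' Returns the `k` conformer ids with the most negative value of the chosen
#' score column (docking score or MM/PBSA binding energy). Ties are broken
#' by lexicographic id order, and a note is emitted when a tie is broken.
#'
#' @param records Conformer table (see [validate_conformers()]).
#' @param key `"docking"` or `"mmpbsa"`.
#' @param k Shortlist size, `1 <= k <= nrow(records)`.
#' @return Character vector of `k` ids (set semantics; returned in score
#'   order).
#' @export
shortlist_conformers <- function(records, key = c("docking", "mmpbsa"), k = 6L) {
  records <- validate_conformers(records)
  key <- match.arg(key)
  if (k < 1 || k > nrow(records)) {
    abort("`k` must be between 1 and the number of records")
  }
  score <- switch(key, docking = records$docking_score,
                  mmpbsa = records$mmpbsa_energy)
  ord <- order(score, records$id)
  if (k < nrow(records) && score[ord[k]] == score[ord[k + 1]]) {
    inform(paste0("shortlist(", key, "): tie at rank ", k,
                  " broken by id order"))
  }
  records$id[ord][seq_len(k)]
}

#' Multi-criteria conformer triage
#'
#' Implements the full selection used to pick substrate binding-model
#' candidates from a docked conformer ensemble:
#' the intersection of the docking-score and MM/PBSA shortlists, filtered by
#' a strict conformational-penalty gate (`penalty < penalty_max`) and a
#' reaction-orientation gate (`reaction_distance <= orientation_max`,
#' substrate meso methylene carbon to FAD N5), then ranked by the configured
#' score, most negative first.
#'
#' Every excluded conformer is recorded with the first criterion it failed;
#' the audit trail is attached as attribute `"exclusions"` and also emitted
#' via `message()`. An empty result is a warning, not an error.
#'
#' @param records Conformer table.
#' @param config [selection_config()].
#' @return Tibble of selected records (all five columns plus `rank`),
#'   ordered by the ranking score. Attribute `"exclusions"` is a tibble
#'   `id`, `reason`.
#' @examples
#' tab <- sim_conformer_table(18, planted = c("M14", "M15"), seed = 1)
#' select_conformers(tab)$id
#' @export
select_conformers <- function(records, config = selection_config()) {
  records <- validate_conformers(records)
  sl_dock <- shortlist_conformers(records, "docking",
                                  min(config$k_docking, nrow(records)))
  sl_pbsa <- shortlist_conformers(records, "mmpbsa",
                                  min(config$k_mmpbsa, nrow(records)))
  reason <- rep(NA_character_, nrow(records))
  reason[!(records$id %in% sl_dock)] <- "outside docking shortlist"
  ok <- is.na(reason)
  reason[ok & !(records$id %in% sl_pbsa)] <- "outside MM/PBSA shortlist"
  ok <- is.na(reason)
  reason[ok & records$penalty >= config$penalty_max] <-
    sprintf("penalty >= %.1f kcal/mol", config$penalty_max)
  ok <- is.na(reason)
  reason[ok & records$reaction_distance > config$orientation_max] <-
    sprintf("reaction distance > %.1f A", config$orientation_max)
  keep <- is.na(reason)

  excl <- tibble(id = records$id[!keep], reason = reason[!keep])
  if (nrow(excl)) {
    inform(paste0("excluded ", nrow(excl), " conformer(s): ",
                  paste(excl$id, " (", excl$reason, ")",
                        sep = "", collapse = "; ")))
  }
  sel <- records[keep, , drop = FALSE]
  score <- switch(config$rank_by, mmpbsa = sel$mmpbsa_energy,
                  docking = sel$docking_score)
  sel <- sel[order(score, sel$id), , drop = FALSE]
  if (nrow(sel) == 0) {
    warn("no conformer satisfies all selection criteria")
  }
  sel$rank <- seq_len(nrow(sel))
  attr(sel, "exclusions") <- excl
  sel
}

#' Read / write a conformer table
#'
#' Five-column table (`id`, `docking_score`, `mmpbsa_energy`, `penalty`,
#' `reaction_distance`); TSV by default, delimiter auto-detected on read.
#'
#' @param records Conformer tibble.
#' @param path File path.
#' @return `read_conformers()` returns the validated tibble.
#' @export
write_conformers <- function(records, path) {
  readr::write_tsv(validate_conformers(records), path)
  invisible(path)
}

#' @rdname write_conformers
#' @export
read_conformers <- function(path) {
  validate_conformers(ppo_read_table(path, schema = conformer_schema()))
}

conformer_schema <- function() {
  list(
    id = list(type = "character"),
    docking_score = list(type = "numeric"),
    mmpbsa_energy = list(type = "numeric"),
    penalty = list(type = "numeric", check = function(x) x >= 0,
                   constraint = "penalty >= 0"),
    reaction_distance = list(type = "numeric", check = function(x) x > 0,
                             constraint = "reaction_distance > 0")
  )
}
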