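#' Simulate a conformer score table with a planted answer
#'
#' Builds a random conformer table in which the `planted` ids are, by
#' construction, the only records that survive the full multi-criteria
#' triage of [select_conformers()]: they sit inside the top-k of both the
#' docking and the MM/PBSA shortlists and pass the penalty and orientation
#' gates. Distractors either fall outside one of the shortlists (their role
#' is to fill the remaining shortlist slots) or fail the penalty gate, so
#' every non-planted record fails at least one criterion regardless of the
#' table size.
#'
#' @param n Total number of records, `n >= length(planted) >= 1`.
#' @param planted Character ids of the records that must be selected.
#' @param seed Integer seed; scores differ between seeds but the selected
#'   set is always exactly `planted`.
#' @param config [selection_config()] the table is planted against.
#' @return A conformer tibble (`id`, `docking_score`, `mmpbsa_energy`,
#'   `penalty`, `reaction_distance`).
#' @examples
#' tab <- sim_conformer_table(18, c("M14", "M15"), seed = 7)
#' suppressMessages(select_conformers(tab))$id
#' @export
sim_conformer_table <- function(n, planted, seed = 1L,
                                config = selection_config()) {
  n <- as.integer(n)
  m <- length(planted)
  if (m < 1) abort("need at least one planted id")
  if (anyDuplicated(planted)) abort("planted ids must be unique")
  if (n < m) abort(paste0("n = ", n, " is too small to hold ", m,
                          " planted ids plus distractors"))

  withr::with_seed(as.integer(seed), {
    runif_rng <- function(k, lo, hi) stats::runif(k, lo, hi)
    kd <- min(config$k_docking, n)
    kp <- min(config$k_mmpbsa, n)
    n_dis <- n - m
    n_fill_dock <- max(0L, min(kd - m, n_dis))
    n_fill_pbsa <- max(0L, min(kp - m, n_dis - n_fill_dock))
    n_rest <- n_dis - n_fill_dock - n_fill_pbsa

    dis_ids <- sprintf("X%03d", seq_len(n_dis))
    if (any(dis_ids %in% planted)) {
      dis_ids <- sprintf("DIS%04d", seq_len(n_dis))
    }

    # Planted records: best in both score columns, pass both gates.
    plant <- tibble(
      id = planted,
      docking_score = runif_rng(m, -15, -14),
      mmpbsa_energy = runif_rng(m, -50, -46),
      penalty = runif_rng(m, 0.5, 0.9 * config$penalty_max),
      reaction_distance = runif_rng(m, 3.0, 0.95 * config$orientation_max)
    )
    # Shortlist fillers: good in exactly one score column; distractors all
    # fail the penalty gate as a second, independent disqualifier.
    fill_dock <- tibble(
      id = head(dis_ids, n_fill_dock),
      docking_score = runif_rng(n_fill_dock, -13.9, -13.0),
      mmpbsa_energy = runif_rng(n_fill_dock, -30, -20),
      penalty = runif_rng(n_fill_dock, config$penalty_max + 0.5,
                          config$penalty_max + 6),
      reaction_distance = runif_rng(n_fill_dock, 3.0, 6.0)
    )
    fill_pbsa <- tibble(
      id = dis_ids[seq_len(n_fill_pbsa) + n_fill_dock],
      docking_score = runif_rng(n_fill_pbsa, -11, -9),
      mmpbsa_energy = runif_rng(n_fill_pbsa, -45, -41),
      penalty = runif_rng(n_fill_pbsa, config$penalty_max + 0.5,
                          config$penalty_max + 6),
      reaction_distance = runif_rng(n_fill_pbsa, 3.0, 6.0)
    )
    rest <- tibble(
      id = tail(dis_ids, n_rest),
      docking_score = runif_rng(n_rest, -11, -9),
      mmpbsa_energy = runif_rng(n_rest, -30, -20),
      penalty = runif_rng(n_rest, config$penalty_max + 0.5,
                          config$penalty_max + 6),
      reaction_distance = runif_rng(n_rest, 3.0, 6.0)
    )
    tab <- dplyr::bind_rows(plant, fill_dock, fill_pbsa, rest)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]

    got <- suppressMessages(select_conformers(tab, config))$id
    if (!setequal(got, planted)) {
      abort("internal error: planted set not recoverable from generated table")
    }
    tab
  })
}
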