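#' 12-10 hydrogen-bond potential
#'
#' Distance-dependent hydrogen-bond energy
#' \deqn{E(r) = \epsilon\left[5\,(r_{eqm}/r)^{12} - 6\,(r_{eqm}/r)^{10}\right]}
#' with its minimum of exactly \eqn{-\epsilon} at \eqn{r = r_{eqm}}. The
#' functional form is a pluggable strategy: pass an alternative via `form`
#' (a function of `r`, `r_eqm`, `epsilon`) to score with a different
#' potential while keeping all downstream book-keeping.
#'
#' @param r Donor-acceptor distance(s), A; must be strictly positive.
#' @param params An [hbond_params()] object.
#' @param form Optional replacement scoring function.
#' @return Energy in kcal/mol, vectorized over `r`.
#' @examples
#' hbe_potential(1.8)   # well depth: -8.4
#' hbe_potential(20)    # dissociated: ~0
#' @export
hbe_potential <- function(r, params = hbond_params(), form = NULL) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    abort("`r` must be finite and strictly positive (distances in A).")
  }
  if (!is.null(form)) {
    return(form(r, params$r_eqm, params$epsilon))
  }
  q <- params$r_eqm / r
  params$epsilon * (5 * q^12 - 6 * q^10)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Check and tidy a distance trajectory
#'
#' A distance trajectory is a data frame with a `time_ps` column and one
#' strictly positive numeric column per labeled donor-acceptor pair, one row
#' per snapshot.
#'
#' @param traj Data frame as above.
#' @return The validated trajectory as a tibble.
#' @keywords internal
validate_trajectory <- function(traj) {
  traj <- as_tibble(traj)
  if (!"time_ps" %in% names(traj)) {
    abort("trajectory must have a `time_ps` column")
  }
  labels <- setdiff(names(traj), "time_ps")
  if (!length(labels)) abort("trajectory has no pair columns")
  if (nrow(traj) < 1) abort("trajectory needs at least one snapshot")
  for (lb in labels) {
    x <- traj[[lb]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      abort(paste0("pair `", lb, "` has non-positive or non-finite distances"))
    }
  }
  traj
}

#' Per-bond hydrogen-bond statistics
#'
#' For each labeled donor-acceptor pair, computes the occupancy (percentage
#' of snapshots with distance below the cutoff), the distance extrema, mean
#' and standard deviation, and the mean and standard deviation of the
#' per-snapshot hydrogen-bond energy. Energies are averaged over *all*
#' snapshots, occupied or not, and standard deviations are population
#' standard deviations of the same per-snapshot series.
#'
#' @param traj Distance trajectory (`time_ps` plus one column per pair).
#' @param params [hbond_params()].
#' @param labels Pairs to summarize; default all. Unknown labels raise an
#'   error listing what is available.
#' @return A tibble with one row per pair: `label`, `occupancy` (percent),
#'   `max_distance`, `min_distance`, `mean_distance`, `sd_distance` (A),
#'   `mean_hbe`, `sd_hbe` (kcal/mol).
#' @seealso [total_hbe()] to aggregate, [hbe_potential()] for the energy
#'   model.
#' @export
hbond_stats <- function(traj, params = hbond_params(), labels = NULL) {
  traj <- validate_trajectory(traj)
  all_labels <- setdiff(names(traj), "time_ps")
  labels <- labels %||% all_labels
  missing <- setdiff(labels, all_labels)
  if (length(missing)) {
    abort(paste0("unknown pair label(s): ", paste(missing, collapse = ", "),
                 "; available: ", paste(all_labels, collapse = ", ")))
  }
  purrr::map_dfr(labels, function(lb) {
    d <- traj[[lb]]
    e <- hbe_potential(d, params)
    tibble(
      label = lb,
      occupancy = 100 * mean(d < params$occupancy_cutoff),
      max_distance = max(d),
      min_distance = min(d),
      mean_distance = mean(d),
      sd_distance = pop_sd(d),
      mean_hbe = mean(e),
      sd_hbe = pop_sd(e)
    )
  })
}

#' Total hydrogen-bond energy over reported bonds
#'
#' Sums `mean_hbe` over the bonds whose occupancy exceeds the reporting
#' threshold (70% by default); bonds below the threshold are excluded and
#' returned for inspection. With the published per-bond energies this
#' reproduces the printed totals: the three M14 bonds give -12.0 kcal/mol
#' and the five M15 bonds -17.3 (printed as -17.4; the addends are rounded).
#'
#' @param stats Tibble from [hbond_stats()] (needs `label`, `occupancy`,
#'   `mean_hbe`).
#' @param params [hbond_params()]; `report_threshold` is the occupancy gate.
#' @return One-row tibble: `thbe` (kcal/mol), `n_bonds`, and list-columns
#'   `contributing` and `excluded` of labels.
#' @export
total_hbe <- function(stats, params = hbond_params()) {
  stats <- as_tibble(stats)
  if (nrow(stats) == 0) {
    return(tibble(thbe = 0, n_bonds = 0L,
                  contributing = list(character()),
                  excluded = list(character())))
  }
  stopifnot(all(c("label", "occupancy", "mean_hbe") %in% names(stats)))
  keep <- stats$occupancy > params$report_threshold * 100
  if (any(!keep)) {
    inform(paste0("excluded from THBE (occupancy <= ",
                  params$report_threshold * 100, "%): ",
                  paste(stats$label[!keep], collapse = ", ")))
  }
  tibble(
    thbe = sum(stats$mean_hbe[keep]),
    n_bonds = sum(keep),
    contributing = list(stats$label[keep]),
    excluded = list(stats$label[!keep])
  )
}

#' Write / read a distance trajectory as TSV
#'
#' Tab-separated, first column `time_ps`, one column per pair label.
#'
#' @param traj Trajectory tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the validated trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(validate_trajectory(traj), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  validate_trajectory(readr::read_tsv(path, show_col_types = FALSE))
}

#' Write a summary table of hydrogen-bond statistics
#'
#' Serializes [hbond_stats()] output plus the [total_hbe()] aggregate in the
#' conventional report layout: label, %, max, min, ave(sd), HBE(sd), THBE.
#'
#' @param stats Tibble from [hbond_stats()].
#' @param path Output TSV path.
#' @param params [hbond_params()].
#' @return The formatted tibble, invisibly.
#' @export
write_hbond_table <- function(stats, path, params = hbond_params()) {
  tot <- total_hbe(stats, params)
  out <- tibble(
    label = stats$label,
    `%` = sprintf("%.1f", stats$occupancy),
    max = sprintf("%.1f", stats$max_distance),
    min = sprintf("%.1f", stats$min_distance),
    `ave(sd)` = sprintf("%.1f (%.2f)", stats$mean_distance, stats$sd_distance),
    `HBE(sd)` = sprintf("%.1f (%.2f)", stats$mean_hbe, stats$sd_hbe),
    THBE = c(sprintf("%.1f", tot$thbe), rep("", nrow(stats) - 1))
  )
  readr::write_tsv(out, path)
  invisible(out)
}
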