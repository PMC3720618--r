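#' Read a delimited table with schema validation
#'
#' Reads TSV or CSV (delimiter auto-detected from the header line, with an
#' explicit override), validates it against a lightweight schema, and
#' returns a tibble. Columns not named in the schema are preserved
#' untouched; schema violations raise an error naming the row, the column
#' and the violated constraint.
#'
#' A schema is a named list, one entry per required column, each a list with
#' `type` (`"numeric"` or `"character"`), and optionally `check` (a
#' vectorized predicate) plus `constraint` (its human-readable description).
#'
#' @param path File path.
#' @param schema Schema as above, or `NULL` for no validation.
#' @param delim `"\t"`, `","`, or `NULL` to auto-detect.
#' @return Tibble.
#' @export
ppo_read_table <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE, col_types = readr::cols(.default = "c"))
  if (is.null(schema)) {
    return(readr::type_convert(tab, col_types = readr::cols()))
  }
  miss <- setdiff(names(schema), names(tab))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in names(schema)) {
    spec <- schema[[col]]
    x <- tab[[col]]
    if (identical(spec$type, "numeric")) {
      num <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(num) & !is.na(x))
      if (length(bad)) {
        abort(sprintf("row %d, column %s: `%s` is not numeric",
                      bad[1], col, x[bad[1]]))
      }
      tab[[col]] <- num
    }
    if (!is.null(spec$check)) {
      ok <- spec$check(tab[[col]])
      bad <- which(!ok)
      if (length(bad)) {
        abort(sprintf("row %d, column %s: violates constraint `%s`",
                      bad[1], col,
                      spec$constraint %||% "check"))
      }
    }
  }
  extra <- setdiff(names(tab), names(schema))
  for (col in extra) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    if (!any(is.na(num) & !is.na(tab[[col]]))) tab[[col]] <- num
  }
  tab
}

#' @rdname ppo_read_table
#' @param x Data frame to write.
#' @export
ppo_write_table <- function(x, path, delim = "\t") {
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Run the whole analysis pipeline
#'
#' Executes the configured stages in order — synthetic-data generation,
#' hydrogen-bond statistics, conformer triage, WHAM free-energy
#' reconstruction, mutation thermodynamics and feedback-kinetics
#' classification — writing per-stage outputs under `out_dir` and returning
#' a machine-readable summary (also serialized as `summary.json` when the
#' jsonlite package is available). All randomness flows from `seed`; two
#' runs with an identical config produce identical outputs. A stage failure
#' aborts with the stage name; outputs of earlier stages are preserved.
#'
#' @param config Named list: `out_dir` (required), `seed` (default 1),
#'   `temperature` (K, default 298.15), `stages` (character subset of
#'   `c("synth", "hbond", "select", "wham", "thermo", "kinetics")`; empty
#'   vector is a no-op). Optional sub-lists `wham` (`n_windows`,
#'   `samples_per_window`, `bin_width`) and `kinetics` (`s0_uM`, `e0_nM`,
#'   `t_max`) override the demonstration problem sizes.
#' @return Summary list, invisibly. Elements (as stages run): `thbe`,
#'   `selected_conformers`, `pmf_dg`, `r2_hppo`, `r2_tobacco`,
#'   `efficiencies`, `kinetics_verdicts`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  seed <- as.integer(config$seed %||% 1L)
  temperature <- config$temperature %||% 298.15
  stages <- config$stages %||%
    c("synth", "hbond", "select", "wham", "thermo", "kinetics")
  known <- c("synth", "hbond", "select", "wham", "thermo", "kinetics")
  if (length(setdiff(stages, known))) {
    abort(paste0("unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    inform(paste0("[pipeline] stage ", name, " (seed ", seed, ")"))
    tryCatch(fun(), error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  run_stage("synth", function() {
    pairs <- tibble(
      label = c("D1", "D2", "D3"),
      mean_distance = c(1.8, 1.9, 2.2),
      sd = c(0.16, 0.19, 0.22),
      target_occupancy = c(0.998, 0.983, 0.925)
    )
    state$traj <- sim_hbond_trajectory(pairs, n_snapshots = 3000,
                                       seed = seed + 11L)
    write_trajectory(state$traj, file.path(out_dir, "trajectory.tsv"))

    wcfg <- config$wham %||% list()
    n_w <- wcfg$n_windows %||% 11L
    spw <- wcfg$samples_per_window %||% 2000L
    state$windows <- sim_umbrella_windows(
      potential = c(0, 0, 1),  # U(x) = x^2, i.e. harmonic with k0 = 2
      centers = seq(-2, 2, length.out = n_w),
      force_constants = 10, n_samples = spw, burn_in = min(200L, spw %/% 4),
      temperature = temperature, seed = seed + 23L)
    write_umbrella(state$windows, file.path(out_dir, "umbrella"))

    kcfg <- config$kinetics %||% list()
    s0 <- kcfg$s0_uM %||% 0.34
    e0 <- kcfg$e0_nM %||% c(0.32, 3.22, 32.22, 96.66)
    t_max <- kcfg$t_max %||% 120
    state$curves <- sim_progress_curves(
      substrate_uM = s0, enzyme_nM = e0,
      times = seq(0, t_max, by = 0.25),
      params = rate_params(k_auto = 0), noise_sd = 0, seed = seed + 37L)
    ppo_write_table(state$curves, file.path(out_dir, "progress_curves.tsv"))
    invisible(NULL)
  })

  run_stage("hbond", function() {
    if (is.null(state$traj)) {
      state$traj <- read_trajectory(file.path(out_dir, "trajectory.tsv"))
    }
    stats <- hbond_stats(state$traj)
    write_hbond_table(stats, file.path(out_dir, "hbond_table.tsv"))
    summary$thbe <<- total_hbe(stats)$thbe
  })

  run_stage("select", function() {
    sel <- suppressMessages(select_conformers(ppo_conformer_demo()))
    write_conformers(sel[names(ppo_conformer_demo())],
                     file.path(out_dir, "selected_conformers.tsv"))
    summary$selected_conformers <<- sel$id
  })

  run_stage("wham", function() {
    if (is.null(state$windows)) {
      state$windows <- read_umbrella(
        file.path(out_dir, "umbrella", "metadata.txt"))
    }
    bw <- (config$wham %||% list())$bin_width %||% 0.1
    prof <- pmf_wham(state$windows, bin_width = bw)
    write_pmf(prof, file.path(out_dir, "pmf.tsv"))
    summary$pmf_dg <<- suppressWarnings(
      pmf_binding_energy(prof, plateau_span = 0.5))
  })

  run_stage("thermo", function() {
    cfg <- thermo_config(temperature = temperature)
    comp <- ppo_ddg_components()
    kin <- ppo_hppo_kinetics()
    hp <- dplyr::inner_join(
      comp[comp$set == "hppo", ],
      dplyr::transmute(ddg_ledger(kin, wt = "Wild-type (WT)", cfg = cfg),
                       mutant = .data$mutant, ddg_expt = .data$ddg_expt),
      by = "mutant")
    hp$ddg_calc <- ddg_calc(hp$ddh, hp$minus_t_dds)
    tb <- dplyr::inner_join(
      comp[comp$set == "mtppo", ],
      dplyr::transmute(ddg_ledger(ppo_tobacco_km(), wt = "WT", cfg = cfg),
                       mutant = .data$mutant, ddg_expt = .data$ddg_expt),
      by = "mutant")
    tb$ddg_calc <- ddg_calc(tb$ddh, tb$minus_t_dds)
    ppo_write_table(dplyr::bind_rows(hp, tb),
                    file.path(out_dir, "ddg_table.tsv"))
    summary$r2_hppo <<- pearson_r2(hp$ddg_calc, hp$ddg_expt)
    summary$r2_tobacco <<- pearson_r2(tb$ddg_calc, tb$ddg_expt)
    eff <- dplyr::mutate(
      kin, efficiency = catalytic_efficiency(.data$kcat_min, .data$km_uM))
    ppo_write_table(eff, file.path(out_dir, "efficiencies.tsv"))
    summary$efficiencies <<- setNames(eff$efficiency, eff$mutant)
  })

  run_stage("kinetics", function() {
    if (is.null(state$curves)) {
      state$curves <- ppo_read_table(file.path(out_dir, "progress_curves.tsv"))
      state$curves$background <- as.logical(state$curves$background)
    }
    fam <- state$curves[!state$curves$background, ]
    verdicts <- classify_feedback(fam)
    ppo_write_table(verdicts, file.path(out_dir, "kinetics_verdicts.tsv"))
    summary$kinetics_verdicts <<- setNames(as.character(verdicts$verdict),
                                           format(verdicts$e0_nM))
  })

  if (length(summary) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
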