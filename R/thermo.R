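#' Binding free energy from a Michaelis constant
#'
#' Under the rapid-equilibration assumption \eqn{K_m \approx K_d}, the
#' binding free energy relative to a 1 M standard state is
#' \eqn{\Delta G_{bind} = RT \ln(K_m / c^0)}, negative for sub-molar
#' \eqn{K_m}. For wild-type tobacco PPO (\eqn{K_m} = 1.17 uM) this gives
#' -8.1 kcal/mol at 298.15 K.
#'
#' @param km_uM Michaelis constant(s) in uM, > 0.
#' @param cfg [thermo_config()].
#' @return Free energy, kcal/mol (vectorized).
#' @examples
#' dg_from_km(1.17)  # -8.09
#' @export
dg_from_km <- function(km_uM, cfg = thermo_config()) {
  if (any(!is.finite(km_uM)) || any(km_uM <= 0)) {
    abort("`km_uM` must be finite and strictly positive")
  }
  rt <- cfg$gas_constant * cfg$temperature
  rt * log(km_uM * 1e-6 / cfg$standard_concentration)
}

#' Mutational binding free-energy shift from a Km ratio
#'
#' \eqn{\Delta\Delta G_{expt} = RT \ln(K_m^{mut} / K_m^{WT})}: positive for
#' a destabilizing mutation (weaker binding, larger \eqn{K_m}), matching
#' the sign convention of published mutant tables. Antisymmetric in its two
#' arguments and additive along mutational paths.
#'
#' @param km_mut,km_wt Michaelis constants (any common unit), > 0.
#' @param cfg [thermo_config()].
#' @return kcal/mol (vectorized over `km_mut`).
#' @examples
#' ddg_from_km(5.63, 2.08)  # M368K: 0.59
#' @export
ddg_from_km <- function(km_mut, km_wt, cfg = thermo_config()) {
  if (any(!is.finite(c(km_mut, km_wt))) || any(km_mut <= 0) || any(km_wt <= 0)) {
    abort("Michaelis constants must be finite and strictly positive")
  }
  cfg$gas_constant * cfg$temperature * log(km_mut / km_wt)
}

#' Calculated free-energy shift from its enthalpic and entropic parts
#'
#' Aggregates the two components produced by a computational mutation scan:
#' \eqn{\Delta\Delta G_{calc} = \Delta\Delta H + (-T\Delta\Delta S)}.
#'
#' @param ddh Enthalpy shift, kcal/mol.
#' @param minus_t_dds Entropy term \eqn{-T\Delta\Delta S}, kcal/mol.
#' @return kcal/mol (vectorized).
#' @export
ddg_calc <- function(ddh, minus_t_dds) {
  if (any(!is.finite(ddh)) || any(!is.finite(minus_t_dds))) {
    abort("components must be finite")
  }
  ddh + minus_t_dds
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-degenerate
#'   variance.
#' @return r-squared in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired values")
  if (var(x) == 0 || var(y) == 0) abort("degenerate variance in `x` or `y`")
  cor(x, y)^2
}

#' Catalytic efficiency kcat / Km
#'
#' @param kcat Turnover number(s), >= 0 (units as given, e.g. min-1).
#' @param km Michaelis constant(s), > 0 (e.g. uM).
#' @return Efficiency in (kcat units)/(km units), e.g. uM-1 min-1.
#' @export
catalytic_efficiency <- function(kcat, km) {
  if (any(km <= 0)) abort("`km` must be strictly positive")
  if (any(kcat < 0)) abort("`kcat` must be non-negative")
  kcat / km
}

#' Lineweaver-Burk estimation of Km and Vmax
#'
#' Ordinary least squares on the double-reciprocal plot
#' \eqn{1/v = (K_m/V_{max})(1/[S]) + 1/V_{max}}: `km = slope/intercept`,
#' `vmax = 1/intercept`, and `kcat = vmax / e0` when the enzyme
#' concentration is supplied.
#'
#' @param data Data frame with columns `substrate` (concentration) and
#'   `velocity` (rate), >= 3 strictly positive points.
#' @param e0 Optional enzyme concentration (same concentration unit as
#'   `vmax` per time unit is desired in).
#' @return An object of class `lb_fit` with elements `km`, `vmax`, `kcat`,
#'   `e0`, `fit` (the underlying `lm`), `data`. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(substrate = c(0.5, 1, 2, 4, 8),
#'                     velocity = 10 * substrate / (2 + substrate))
#' fit_lineweaver_burk(d)
#' @export
fit_lineweaver_burk <- function(data, e0 = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("substrate", "velocity") %in% names(data)))
  s <- data$substrate
  v <- data$velocity
  if (length(s) < 3) abort("need at least 3 substrate/velocity points")
  if (any(s <= 0) || any(v <= 0)) {
    abort("substrate and velocity must be strictly positive")
  }
  inv_s <- 1 / s
  inv_v <- 1 / v
  fit <- lm(inv_v ~ inv_s)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (intercept <= 0) {
    abort("data inconsistent with saturation kinetics: non-positive 1/Vmax intercept")
  }
  vmax <- 1 / intercept
  structure(
    list(km = slope / intercept, vmax = vmax,
         kcat = if (is.null(e0)) NA_real_ else vmax / e0,
         e0 = e0 %||% NA_real_, fit = fit, data = data),
    class = "lb_fit"
  )
}

#' @export
print.lb_fit <- function(x, ...) {
  cat(sprintf("<lb_fit> Km = %.4g, Vmax = %.4g", x$km, x$vmax))
  if (!is.na(x$kcat)) cat(sprintf(", kcat = %.4g (e0 = %.4g)", x$kcat, x$e0))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lb_fit <- function(x, ...) {
  tibble(term = c("km", "vmax", "kcat"),
         estimate = c(x$km, x$vmax, x$kcat))
}

#' @exportS3Method generics::glance
glance.lb_fit <- function(x, ...) {
  tibble(km = x$km, vmax = x$vmax, kcat = x$kcat, e0 = x$e0,
         r_squared = summary(x$fit)$r.squared, n = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.lb_fit <- function(object, ...) {
  df <- tibble(inv_s = 1 / object$data$substrate,
               inv_v = 1 / object$data$velocity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inv_s, y = .data$inv_v)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = coef(object$fit)[1],
                         slope = coef(object$fit)[2]) +
    ggplot2::labs(x = "1/[S]", y = "1/v") +
    ggplot2::theme_minimal()
}

#' Mutational thermodynamics ledger from a Km table
#'
#' Takes a table of per-mutant Michaelis constants, computes
#' \eqn{\Delta\Delta G_{expt}} against the wild-type row, and (when the
#' enthalpic/entropic components of a computational mutation scan are
#' present) \eqn{\Delta\Delta G_{calc}}, returning one tidy row per mutant.
#'
#' @param km_table Data frame with `mutant` and `km_uM` columns; optional
#'   `ddh` and `minus_t_dds` columns add the calculated side.
#' @param wt Name of the wild-type row (dropped from the output).
#' @param cfg [thermo_config()].
#' @return Tibble with `mutant`, `km_uM`, `ddg_expt` and, when available,
#'   `ddh`, `minus_t_dds`, `ddg_calc`.
#' @examples
#' ddg_ledger(ppo_tobacco_km(), wt = "WT")
#' @export
ddg_ledger <- function(km_table, wt = "WT", cfg = thermo_config()) {
  km_table <- as_tibble(km_table)
  stopifnot(all(c("mutant", "km_uM") %in% names(km_table)))
  if (!wt %in% km_table$mutant) {
    abort(paste0("wild-type row `", wt, "` not found; rows: ",
                 paste(km_table$mutant, collapse = ", ")))
  }
  km_wt <- km_table$km_uM[km_table$mutant == wt][1]
  out <- km_table |>
    dplyr::filter(.data$mutant != wt) |>
    dplyr::mutate(ddg_expt = ddg_from_km(.data$km_uM, km_wt, cfg))
  if (all(c("ddh", "minus_t_dds") %in% names(out))) {
    out <- dplyr::mutate(out, ddg_calc = ddg_calc(.data$ddh, .data$minus_t_dds))
  }
  out
}
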