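logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Histogram window samples on a shared grid anchored at multiples of
# bin_width, so that identical inputs always land in identical bins.
wham_bins <- function(samples_list, bin_width) {
  lo <- floor(min(unlist(samples_list)) / bin_width) * bin_width
  hi <- max(unlist(samples_list))
  n_bins <- max(1L, ceiling((hi - lo) / bin_width + 1e-9))
  edges <- lo + bin_width * (0:n_bins)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  counts <- vapply(samples_list, function(s) {
    idx <- pmin(pmax(floor((s - lo) / bin_width) + 1, 1L), n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  list(centers = centers, counts = counts)  # counts: n_bins x n_windows
}

# Windows must form one chain of mutual histogram overlap, otherwise the
# relative window free energies are undetermined.
check_overlap <- function(centers, counts) {
  n_w <- ncol(counts)
  if (n_w == 1) return(invisible(TRUE))
  occ <- counts > 0
  comp <- seq_len(n_w)
  repeat {
    changed <- FALSE
    for (i in seq_len(n_w - 1)) {
      for (j in seq.int(i + 1, n_w)) {
        if (comp[i] != comp[j] && any(occ[, i] & occ[, j])) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    spans <- vapply(split(seq_len(n_w), comp), function(ix) {
      b <- which(rowSums(occ[, ix, drop = FALSE]) > 0)
      c(centers[min(b)], centers[max(b)])
    }, numeric(2))
    spans <- spans[, order(spans[1, ]), drop = FALSE]
    gap_lo <- spans[2, 1]
    gap_hi <- spans[1, 2]
    abort(sprintf(
      "umbrella windows do not overlap: no samples bridge the interval [%.3g, %.3g] A",
      gap_lo, gap_hi))
  }
  invisible(TRUE)
}

#' WHAM reconstruction of a potential of mean force
#'
#' Combines biased umbrella-window histograms into one unbiased free-energy
#' profile with the weighted histogram analysis method. The unbiased
#' probability of bin \eqn{b} is
#' \deqn{P_b = \frac{\sum_i n_{ib}}{\sum_i N_i \exp[(f_i - w_i(x_b))/k_BT]}}
#' and the window free-energy constants are refreshed as
#' \deqn{f_i = -k_BT \ln \sum_b P_b \exp[-w_i(x_b)/k_BT],}
#' iterated (in log space, with optional damping when the update
#' oscillates) until the largest change in any \eqn{f_i} drops below `tol`.
#' \eqn{W(x) = -k_BT \ln P(x)}, shifted so its minimum is zero.
#'
#' Bins never visited by any window are reported with `free_energy = NA`
#' (never zero), and are excluded from the self-consistency sums. Windows
#' whose histograms do not chain-overlap make the relative constants
#' undetermined and raise an error naming the unbridged interval.
#'
#' @param windows An `umbrella_windows` object.
#' @param bin_width Histogram bin width (A); the 0.1 A default matches the
#'   finest window spacing in common use.
#' @param tol Convergence tolerance on the window constants (kcal/mol).
#' @param max_iter Iteration cap; non-convergence flags the result rather
#'   than erroring.
#' @param damping Fractional step applied when successive updates grow
#'   instead of shrink.
#' @return A tibble of class `ppo_pmf` with columns `coordinate`,
#'   `free_energy`, `count`, and attributes `converged`, `iterations`,
#'   `window_f` (the constants \eqn{f_i}), `temperature`, `bin_width`.
#' @export
pmf_wham <- function(windows, bin_width = 0.1, tol = 1e-6,
                     max_iter = 100000L, damping = 0.5) {
  stopifnot(inherits(windows, "umbrella_windows"), tol > 0, bin_width > 0)
  w_tbl <- windows$windows
  kt <- kT(windows$temperature)
  h <- wham_bins(w_tbl$samples, bin_width)
  check_overlap(h$centers, h$counts)

  M_b <- rowSums(h$counts)
  occ <- M_b > 0
  xb <- h$centers[occ]
  Mb <- M_b[occ]
  N_i <- lengths(w_tbl$samples)
  # bias matrix: occupied bins x windows, in units of kT
  w_mat <- outer(xb, seq_len(nrow(w_tbl)), function(x, i) {
    bias_energy(x, w_tbl$center[i], w_tbl$force_constant[i],
                windows$bias_convention)
  }) / kt

  g <- rep(0, nrow(w_tbl))          # f_i / kT
  lnN <- log(N_i)
  lnM <- log(Mb)
  prev_delta <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # ln denom_b = logsumexp_i [ln N_i + g_i - w_ib]
    A <- sweep(-w_mat, 2, lnN + g, `+`)   # bins x windows
    row_max <- apply(A, 1, max)
    ln_denom <- row_max + log(rowSums(exp(A - row_max)))
    lnP <- lnM - ln_denom
    lnP <- lnP - logsumexp(lnP)           # normalize
    # g_i_new = -logsumexp_b [lnP_b - w_ib]
    B <- lnP - w_mat
    col_max <- apply(B, 2, max)
    g_new <- -(col_max + log(colSums(exp(sweep(B, 2, col_max, `-`)))))
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g)) * kt
    if (delta > prev_delta) {
      g <- g + damping * (g_new - g)
    } else {
      g <- g_new
    }
    prev_delta <- delta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("WHAM did not converge in %d iterations (last max |df| = %.3g kcal/mol)",
                 iter, prev_delta))
  }

  A <- sweep(-w_mat, 2, lnN + g, `+`)
  row_max <- apply(A, 1, max)
  lnP <- lnM - (row_max + log(rowSums(exp(A - row_max))))
  W <- rep(NA_real_, length(h$centers))
  W[occ] <- -kt * lnP
  W <- W - min(W, na.rm = TRUE)

  out <- tibble(coordinate = h$centers, free_energy = W, count = M_b)
  structure(out,
            class = c("ppo_pmf", class(out)),
            converged = converged, iterations = iter,
            window_f = kt * g, temperature = windows$temperature,
            bin_width = bin_width)
}

#' Binding free energy from a PMF profile
#'
#' The depth of the bound-state minimum relative to the dissociated plateau:
#' \eqn{\Delta G_{bind} = -(\bar W_{plateau} - W_{min})}, where the plateau
#' is the trailing `plateau_span` of the profile. A profile that climbs to a
#' plateau 10.2 kcal/mol above its minimum therefore gives -10.2 kcal/mol.
#'
#' @param profile `ppo_pmf` tibble.
#' @param plateau_span Length (A) of the trailing stretch averaged as the
#'   plateau; the profile must extend at least this far beyond its global
#'   minimum.
#' @param slope_warn Warn "profile not converged" when the absolute fitted
#'   slope over the plateau exceeds this (kcal/mol/A).
#' @return Binding free energy, kcal/mol (negative for a bound state).
#' @export
pmf_binding_energy <- function(profile, plateau_span = 2, slope_warn = 0.1) {
  prof <- profile[!is.na(profile$free_energy), ]
  if (nrow(prof) < 2) abort("profile has fewer than two sampled bins")
  x_min <- prof$coordinate[which.min(prof$free_energy)]
  x_hi <- max(prof$coordinate)
  if (x_hi - x_min < plateau_span) {
    abort(sprintf(
      "profile extends only %.3g A beyond its minimum; plateau_span = %.3g",
      x_hi - x_min, plateau_span))
  }
  pl <- prof[prof$coordinate > x_hi - plateau_span, ]
  if (nrow(pl) >= 3) {
    slope <- unname(coef(lm(free_energy ~ coordinate, data = pl))[2])
    if (abs(slope) > slope_warn) {
      warn(sprintf("profile not converged: plateau slope %.3g kcal/mol/A", slope))
    }
  }
  -(mean(pl$free_energy) - min(prof$free_energy))
}

#' Convergence check by leading-fraction reanalysis
#'
#' Reruns WHAM on the leading fraction of every window's samples, for each
#' requested fraction, and reports the largest pairwise free-energy
#' deviation over the commonly well-sampled bins. Indistinguishable
#' sub-fraction profiles indicate converged sampling.
#'
#' @param windows `umbrella_windows` object.
#' @param fractions Fractions in (0, 1] of each window's samples to keep.
#' @param min_count Bins enter the comparison only when every sub-profile
#'   holds at least this many counts there (sparse edge bins are pure
#'   noise).
#' @param ... Passed to [pmf_wham()].
#' @return List of class `pmf_convergence`: `profiles` (named by fraction),
#'   `max_deviation` (kcal/mol), and the pairwise `deviations` tibble.
#' @export
pmf_convergence <- function(windows, fractions = c(0.6, 0.8, 1.0),
                            min_count = 20, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  profiles <- purrr::map(fractions, function(f) {
    sub <- windows
    sub$windows$samples <- purrr::map(windows$windows$samples, function(s) {
      head(s, max(1L, floor(length(s) * f)))
    })
    pmf_wham(sub, ...)
  })
  names(profiles) <- sprintf("%g", fractions)

  pairs <- utils::combn(seq_along(profiles), 2, simplify = FALSE)
  devs <- purrr::map_dfr(pairs, function(ij) {
    a <- profiles[[ij[1]]]
    b <- profiles[[ij[2]]]
    m <- dplyr::inner_join(
      tibble(coordinate = a$coordinate, wa = a$free_energy, ca = a$count),
      tibble(coordinate = b$coordinate, wb = b$free_energy, cb = b$count),
      by = "coordinate")
    m <- m[!is.na(m$wa) & !is.na(m$wb) & m$ca >= min_count & m$cb >= min_count, ]
    tibble(frac_a = names(profiles)[ij[1]], frac_b = names(profiles)[ij[2]],
           deviation = if (nrow(m)) max(abs(m$wa - m$wb)) else NA_real_)
  })
  structure(list(profiles = profiles,
                 deviations = devs,
                 max_deviation = max(devs$deviation, na.rm = TRUE)),
            class = "pmf_convergence")
}

#' @export
print.pmf_convergence <- function(x, ...) {
  cat("<pmf_convergence> fractions:", paste(names(x$profiles), collapse = ", "),
      "| max pairwise deviation:", sprintf("%.4g kcal/mol", x$max_deviation), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppo_pmf <- function(x, ...) {
  tibble(coordinate = x$coordinate, free_energy = x$free_energy,
         count = x$count)
}

#' @exportS3Method generics::glance
glance.ppo_pmf <- function(x, ...) {
  tibble(n_bins = nrow(x), n_sampled = sum(x$count > 0),
         converged = attr(x, "converged"),
         iterations = attr(x, "iterations"),
         temperature = attr(x, "temperature"),
         bin_width = attr(x, "bin_width"))
}

#' Plot a PMF profile
#'
#' @param object `ppo_pmf` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ppo_pmf <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$free_energy), ],
                  ggplot2::aes(x = .data$coordinate, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "W(ξ) (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Write a PMF profile as TSV (`coordinate  free_energy  count`)
#'
#' @param profile `ppo_pmf` tibble.
#' @param path Output path.
#' @export
write_pmf <- function(profile, path) {
  readr::write_tsv(tidy(profile), path)
  invisible(path)
}
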