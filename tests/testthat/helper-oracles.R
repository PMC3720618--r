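# Independent oracles used by unit and acceptance tests. Each one is a
# deliberately different route to the quantity it checks and must stay
# independent of the implementation in R/.

# Brute-force evaluation of the conformer triage gates: explicit sorting
# and row-by-row set logic, no shared code with select_conformers().
oracle_conformer_gates <- function(records, config = selection_config()) {
  records <- as.data.frame(records)
  kd <- min(config$k_docking, nrow(records))
  kp <- min(config$k_mmpbsa, nrow(records))
  by_dock <- records[order(records$docking_score, records$id), "id"][seq_len(kd)]
  by_pbsa <- records[order(records$mmpbsa_energy, records$id), "id"][seq_len(kp)]
  keep <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$id %in% by_dock && r$id %in% by_pbsa &&
        r$penalty < config$penalty_max &&
        r$reaction_distance <= config$orientation_max) {
      keep <- c(keep, r$id)
    }
  }
  sort(keep)
}

# WHAM by direct convex minimization (gradient-based) of the standard
# maximum-likelihood objective in the window constants, instead of the
# fixed-point iteration used by pmf_wham(). Histograms are rebuilt here
# with the same deterministic binning rule so both see identical input.
oracle_wham <- function(windows, bin_width) {
  kt <- ppobind::kT(windows$temperature)
  samples <- windows$windows$samples
  lo <- floor(min(unlist(samples)) / bin_width) * bin_width
  hi <- max(unlist(samples))
  n_bins <- max(1L, ceiling((hi - lo) / bin_width + 1e-9))
  centers <- lo + bin_width * (seq_len(n_bins) - 0.5)
  counts <- sapply(samples, function(s) {
    idx <- pmin(pmax(floor((s - lo) / bin_width) + 1, 1L), n_bins)
    tabulate(idx, nbins = n_bins)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(samples))
  M <- rowSums(counts)
  occ <- M > 0
  xb <- centers[occ]
  Mb <- M[occ]
  Ni <- lengths(samples)
  pref <- if (windows$bias_convention == "half_k") 0.5 else 1
  wmat <- sapply(seq_along(samples), function(i) {
    pref * windows$windows$force_constant[i] *
      (xb - windows$windows$center[i])^2
  }) / kt  # bins x windows

  nw <- length(Ni)
  obj <- function(gfree) {
    g <- c(0, gfree)
    a <- sweep(-wmat, 2, log(Ni) + g, `+`)
    m <- apply(a, 1, max)
    lden <- m + log(rowSums(exp(a - m)))
    -sum(Ni * g) + sum(Mb * lden)
  }
  grad <- function(gfree) {
    g <- c(0, gfree)
    a <- sweep(-wmat, 2, log(Ni) + g, `+`)
    m <- apply(a, 1, max)
    den <- rowSums(exp(a - m))
    p <- exp(a - m) / den            # bins x windows
    (colSums(Mb * p) - Ni)[-1]
  }
  fit <- stats::optim(rep(0, nw - 1), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  g <- c(0, fit$par)
  a <- sweep(-wmat, 2, log(Ni) + g, `+`)
  m <- apply(a, 1, max)
  lnP <- log(Mb) - (m + log(rowSums(exp(a - m))))
  W <- -kt * lnP
  data.frame(coordinate = xb, free_energy = W - min(W))
}

# Textbook Pearson correlation, written out in sums.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# A random conformer table with no structure at all (for gate-oracle
# equivalence sweeps); distinct uniform scores make ties impossible.
random_conformer_table <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("C%03d", seq_len(n)),
      docking_score = stats::runif(n, -15, -8),
      mmpbsa_energy = stats::runif(n, -50, -15),
      penalty = stats::runif(n, 0, 12),
      reaction_distance = stats::runif(n, 2.5, 7)
    )
  })
}

# Integrated autocorrelation time (initial positive sequence), for
# standard-error corrections on Markov-chain samples.
ess_tau <- function(x, max_lag = 200) {
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  1 + 2 * sum(ac)
}
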