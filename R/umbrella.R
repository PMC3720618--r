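#' Turn a potential specification into a function
#'
#' Accepts a function of the coordinate (A) returning kcal/mol, a numeric
#' vector of polynomial coefficients in ascending powers, or a data frame of
#' knots (`x`, `energy`) interpolated with a natural cubic spline.
#'
#' @param potential Function, numeric vector, or knot data frame.
#' @return A vectorized function `U(x)`.
#' @export
as_potential <- function(potential) {
  if (is.function(potential)) return(potential)
  if (is.numeric(potential)) {
    coefs <- potential
    return(function(x) {
      out <- 0
      for (j in seq_along(coefs)) out <- out + coefs[j] * x^(j - 1)
      out
    })
  }
  if (is.data.frame(potential)) {
    stopifnot(all(c("x", "energy") %in% names(potential)))
    return(stats::splinefun(potential$x, potential$energy, method = "natural"))
  }
  abort("`potential` must be a function, polynomial coefficients, or knots")
}

#' Harmonic umbrella bias
#'
#' Bias energy of window `i` at coordinate `x`. Two conventions are
#' supported because restraint "force constants" are quoted ambiguously
#' across MD codes: `half_k` means \eqn{w(x) = k/2 (x - x_0)^2}; `full_k`
#' is the AMBER restraint convention \eqn{w(x) = k (x - x_0)^2}.
#'
#' @param x Coordinate (A).
#' @param center Window center (A).
#' @param force_constant kcal mol-1 A-2.
#' @param convention `"half_k"` (default) or `"full_k"`.
#' @return Bias energy, kcal/mol.
#' @export
bias_energy <- function(x, center, force_constant,
                        convention = c("half_k", "full_k")) {
  convention <- match.arg(convention)
  pref <- if (convention == "half_k") 0.5 else 1
  pref * force_constant * (x - center)^2
}

#' Simulate umbrella-sampling windows by Metropolis Monte Carlo
#'
#' Draws, for each window, samples from the biased Boltzmann density
#' \eqn{\propto \exp[-(U(x) + w_i(x))/k_BT]} by random-walk Metropolis.
#' A Monte Carlo sampler is used rather than molecular dynamics because a
#' WHAM estimator only needs correctly distributed samples, not dynamics.
#' The first `burn_in` steps of each chain are discarded and the acceptance
#' rate is stored per window; an acceptance rate of zero raises an error
#' suggesting a smaller `proposal_width`.
#'
#' @param potential True potential of mean force along the coordinate; see
#'   [as_potential()].
#' @param centers Strictly increasing window centers (A).
#' @param force_constants Bias force constants (kcal mol-1 A-2), recycled to
#'   `length(centers)`.
#' @param n_samples Metropolis steps per window (`> burn_in`).
#' @param burn_in Discarded leading steps, `>= 0`.
#' @param proposal_width Gaussian random-walk step (A).
#' @param temperature Kelvin.
#' @param bias Bias convention, see [bias_energy()].
#' @param seed Integer seed; each window uses an independent derived stream,
#'   so the whole window set is reproducible bit-for-bit.
#' @return An object of class `umbrella_windows`: list with `windows` (a
#'   tibble of `center`, `force_constant`, `acceptance` and a `samples`
#'   list-column), `temperature`, `bias_convention`.
#' @examples
#' uw <- sim_umbrella_windows(function(x) 0 * x, centers = 0,
#'                            force_constants = 10, n_samples = 2000,
#'                            seed = 1)
#' sd(uw$windows$samples[[1]])^2  # ~ kT / k
#' @export
sim_umbrella_windows <- function(potential, centers, force_constants,
                                 n_samples = 10000L, burn_in = 500L,
                                 proposal_width = 0.5, temperature = 298.15,
                                 bias = c("half_k", "full_k"), seed = 1L) {
  bias <- match.arg(bias)
  U <- as_potential(potential)
  stopifnot(length(centers) >= 1, all(diff(centers) > 0),
            n_samples > burn_in, burn_in >= 0, proposal_width > 0)
  force_constants <- rep_len(force_constants, length(centers))
  if (any(force_constants <= 0)) abort("force constants must be positive")
  beta <- 1 / kT(temperature)

  one_window <- function(center, k, wseed) {
    withr::with_seed(wseed, {
      x <- center
      ux <- U(x) + bias_energy(x, center, k, bias)
      xs <- numeric(n_samples)
      n_acc <- 0L
      steps <- stats::rnorm(n_samples, 0, proposal_width)
      us <- stats::runif(n_samples)
      for (t in seq_len(n_samples)) {
        xp <- x + steps[t]
        up <- U(xp) + bias_energy(xp, center, k, bias)
        if (up <= ux || us[t] < exp(-beta * (up - ux))) {
          x <- xp
          ux <- up
          n_acc <- n_acc + 1L
        }
        xs[t] <- x
      }
      list(samples = xs[(burn_in + 1):n_samples],
           acceptance = n_acc / n_samples)
    })
  }

  wseeds <- as.integer(seed) + seq_along(centers) - 1L
  res <- purrr::pmap(list(centers, force_constants, wseeds), one_window)
  acc <- vapply(res, `[[`, numeric(1), "acceptance")
  if (any(acc == 0)) {
    abort(paste0("zero Metropolis acceptance in window(s) at ",
                 paste(centers[acc == 0], collapse = ", "),
                 " A; reduce `proposal_width`"))
  }
  structure(
    list(
      windows = tibble(center = centers, force_constant = force_constants,
                       acceptance = acc,
                       samples = purrr::map(res, "samples")),
      temperature = temperature,
      bias_convention = bias
    ),
    class = "umbrella_windows"
  )
}

#' Construct an umbrella window set from raw samples
#'
#' @param centers,force_constants,samples Window definitions; `samples` is a
#'   list of numeric vectors (>= 1 value each).
#' @param temperature Kelvin.
#' @param bias Bias convention.
#' @return `umbrella_windows` object.
#' @export
umbrella_windows <- function(centers, force_constants, samples,
                             temperature = 298.15,
                             bias = c("half_k", "full_k")) {
  bias <- match.arg(bias)
  force_constants <- rep_len(force_constants, length(centers))
  stopifnot(length(samples) == length(centers),
            all(force_constants > 0),
            all(lengths(samples) >= 1))
  structure(
    list(windows = tibble(center = centers, force_constant = force_constants,
                          acceptance = NA_real_, samples = samples),
         temperature = temperature, bias_convention = bias),
    class = "umbrella_windows"
  )
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat("<umbrella_windows> ", nrow(x$windows), " windows, ",
      sum(lengths(x$windows$samples)), " samples total, T = ",
      x$temperature, " K, bias = ", x$bias_convention, "\n", sep = "")
  invisible(x)
}

#' Write / read umbrella windows in the conventional file layout
#'
#' One two-column whitespace text file per window (`time  coordinate`) plus
#' a metadata file with one line per window, `path  center  force_constant`
#' — the de-facto input convention of standalone WHAM codes. Temperature
#' and bias convention are stored as `#`-comment header lines that other
#' tools ignore.
#'
#' @param uw `umbrella_windows` object.
#' @param dir Output directory (created if needed).
#' @param meta Metadata file name within `dir`.
#' @return `write_umbrella()` the metadata path invisibly; `read_umbrella()`
#'   the reconstructed `umbrella_windows`.
#' @export
write_umbrella <- function(uw, dir, meta = "metadata.txt") {
  stopifnot(inherits(uw, "umbrella_windows"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("window_%03d.dat", seq_len(nrow(uw$windows)))
  for (i in seq_len(nrow(uw$windows))) {
    s <- uw$windows$samples[[i]]
    readr::write_tsv(tibble(time = seq_along(s), coordinate = s),
                     file.path(dir, paths[i]), col_names = FALSE)
  }
  meta_path <- file.path(dir, meta)
  hdr <- c(sprintf("# temperature %g", uw$temperature),
           sprintf("# bias %s", uw$bias_convention))
  body <- sprintf("%s\t%.10g\t%.10g", paths, uw$windows$center,
                  uw$windows$force_constant)
  writeLines(c(hdr, body), meta_path)
  invisible(meta_path)
}

#' @rdname write_umbrella
#' @param meta_path Path to the metadata file; window files are resolved
#'   relative to its directory.
#' @param temperature,bias Overrides; by default taken from the `#` header
#'   lines (298.15 K / `half_k` if absent).
#' @export
read_umbrella <- function(meta_path, temperature = NULL, bias = NULL) {
  lines <- readLines(meta_path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(temperature)) {
    m <- grep("temperature", hdr, value = TRUE)
    temperature <- if (length(m)) as.numeric(sub(".*temperature\\s+", "", m[1])) else 298.15
  }
  if (is.null(bias)) {
    m <- grep("bias", hdr, value = TRUE)
    bias <- if (length(m)) sub(".*bias\\s+", "", m[1]) else "half_k"
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(paste0("metadata line ", bad[1], ": need `path center force_constant`"))
  }
  dir <- dirname(meta_path)
  samples <- purrr::map(parts, function(p) {
    tab <- readr::read_table(file.path(dir, p[1]), col_names = c("time", "coordinate"),
                             col_types = "dd")
    tab$coordinate
  })
  umbrella_windows(
    centers = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    force_constants = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
    samples = samples, temperature = temperature, bias = bias
  )
}
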