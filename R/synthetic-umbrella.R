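# Analytic PMFs and Boltzmann sampling of umbrella windows under harmonic
# bias. Stands in for biased MD: window i samples the density
# proportional to exp(-[dG(x) + k/2 (x - x_i)^2] / RT) by Metropolis MC.

#' Specify an analytic potential of mean force
#'
#' Three functional forms are available. `gaussian_well` is
#' `-well_depth * exp(-(r - well_center)^2 / (2 well_width^2))`;
#' `hard_wall_plus_well` adds a steep exponential repulsion
#' `500 * exp(-(r - r_min) / 0.1)` kJ/mol rising at the lower range edge;
#' `flat` is identically zero. `well_depth >= 0` denotes the depth of
#' attraction: the minimum of the Gaussian well is `-well_depth`.
#'
#' @param form `"gaussian_well"`, `"hard_wall_plus_well"` or `"flat"`.
#' @param well_depth depth of attraction (kJ/mol, >= 0).
#' @param well_center well position (nm).
#' @param well_width Gaussian width (nm).
#' @param r_range support `[r_lo, r_hi]` (nm), ordered.
#' @return Object of class `"analytic_pmf"`; call it like a function,
#'   `pmf$fun(r)`, for the free energy in kJ/mol.
#' @export
analytic_pmf <- function(form = c("gaussian_well", "hard_wall_plus_well",
                                  "flat"),
                         well_depth = 0, well_center = NA_real_,
                         well_width = NA_real_, r_range = c(3, 8)) {
  form <- match.arg(form)
  r_range <- as.numeric(r_range)
  if (length(r_range) != 2L || r_range[1] >= r_range[2]) {
    stop("r_range must be ordered [lo, hi]")
  }
  if (well_depth < 0) stop("well_depth must be >= 0 (depth of attraction)")
  if (form != "flat" && (!is.finite(well_center) || !is.finite(well_width))) {
    stop("well_center and well_width are required for form '", form, "'")
  }
  fun <- switch(form,
    flat = function(r) rep(0, length(r)),
    gaussian_well = function(r) {
      -well_depth * exp(-(r - well_center)^2 / (2 * well_width^2))
    },
    hard_wall_plus_well = function(r) {
      -well_depth * exp(-(r - well_center)^2 / (2 * well_width^2)) +
        500 * exp(-(r - r_range[1]) / 0.1)
    })
  structure(list(form = form, well_depth = well_depth,
                 well_center = well_center, well_width = well_width,
                 r_range = r_range, fun = fun),
            class = "analytic_pmf")
}

#' Specify an umbrella-sampling protocol
#'
#' Defaults follow the standard fragment-fragment layout: 51 windows with
#' centers from 3.0 to 8.0 nm in 0.1 nm steps and a harmonic force constant
#' of 1000 kJ/mol/nm^2 at 300 K.
#'
#' @param window_centers strictly increasing restraint centers (nm).
#' @param spring_constant harmonic force constant (kJ/mol/nm^2), > 0.
#' @param samples_per_window samples kept per window.
#' @param temperature temperature (K).
#' @param seed integer RNG seed.
#' @return Object of class `"umbrella_protocol"`.
#' @export
umbrella_protocol <- function(window_centers = seq(3, 8, by = 0.1),
                              spring_constant = 1000,
                              samples_per_window = 5000L,
                              temperature = 300, seed = 1L) {
  window_centers <- as.numeric(window_centers)
  if (any(diff(window_centers) <= 0)) {
    stop("window_centers must be strictly increasing")
  }
  if (spring_constant <= 0) stop("spring_constant must be > 0")
  if (samples_per_window < 1L) stop("samples_per_window must be >= 1")
  structure(list(window_centers = window_centers,
                 spring_constant = spring_constant,
                 samples_per_window = as.integer(samples_per_window),
                 temperature = temperature, seed = as.integer(seed)),
            class = "umbrella_protocol")
}

#' Construct an umbrella window set from raw samples
#'
#' @param centers window centers (nm), sorted.
#' @param spring_constant harmonic force constant (kJ/mol/nm^2).
#' @param samples list (one element per window) of sampled reaction
#'   coordinates (nm).
#' @param temperature temperature (K).
#' @return Object of class `"umbrella_windows"`.
#' @export
umbrella_windows <- function(centers, spring_constant, samples,
                             temperature = 300) {
  centers <- as.numeric(centers)
  if (length(samples) != length(centers)) {
    stop("need one sample vector per window center")
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("window centers must be strictly increasing")
  }
  ns <- vapply(samples, length, 1L)
  if (any(ns < 100L)) {
    warning("window(s) ", paste(which(ns < 100L), collapse = ", "),
            " have fewer than 100 samples")
  }
  structure(list(centers = centers, spring_constant = spring_constant,
                 samples = lapply(samples, as.numeric),
                 temperature = temperature),
            class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  ns <- vapply(x$samples, length, 1L)
  cat("Umbrella window set: ", length(x$centers), " windows, centers ",
      sprintf("%.2f", min(x$centers)), "..", sprintf("%.2f", max(x$centers)),
      " nm\n", sep = "")
  cat(sprintf("  k = %g kJ/mol/nm^2, T = %g K, samples/window: %d..%d\n",
              x$spring_constant, x$temperature, min(ns), max(ns)))
  invisible(x)
}

#' Sample umbrella windows from an analytic PMF
#'
#' Per window, a vectorised bank of independent Metropolis chains samples
#' the biased density `exp(-[dG(x) + k/2 (x - x_i)^2] / RT)` restricted to
#' the PMF's support. Chains use 1000 burn-in steps and 10x thinning so the
#' kept samples are effectively decorrelated; an overall acceptance rate
#' below 0.05 aborts with an error (pathological spec).
#'
#' @param pmf an [analytic_pmf()].
#' @param protocol an [umbrella_protocol()]; all centers must lie inside the
#'   PMF's `r_range`.
#' @param burn_in,thin,n_chains Metropolis controls (defaults 1000, 10, and
#'   up to 256 parallel chains).
#' @return An [umbrella_windows()] set.
#' @export
gen_umbrella_windows <- function(pmf, protocol, burn_in = 1000L, thin = 10L,
                                 n_chains = 256L) {
  stopifnot(inherits(pmf, "analytic_pmf"),
            inherits(protocol, "umbrella_protocol"))
  rng <- pmf$r_range
  ctr <- protocol$window_centers
  if (any(ctr < rng[1]) || any(ctr > rng[2])) {
    stop("all window centers must lie inside the PMF r_range")
  }
  set.seed(protocol$seed)
  rt <- rt_kj(protocol$temperature)
  k <- protocol$spring_constant
  sd_h <- sqrt(rt / k)          # harmonic width; also the proposal scale
  prop_sd <- 2.4 * sd_h
  n_keep_total <- protocol$samples_per_window
  m <- min(as.integer(n_chains), n_keep_total)
  keep_per_chain <- ceiling(n_keep_total / m)

  u_bias <- function(x, c0) {
    u <- pmf$fun(x) + 0.5 * k * (x - c0)^2
    u[x < rng[1] | x > rng[2]] <- Inf
    u
  }

  samples <- vector("list", length(ctr))
  for (w in seq_along(ctr)) {
    c0 <- ctr[w]
    x <- pmin(pmax(c0 + stats::rnorm(m, 0, sd_h), rng[1]), rng[2])
    u <- u_bias(x, c0)
    n_steps <- burn_in + thin * keep_per_chain
    kept <- matrix(NA_real_, keep_per_chain, m)
    n_acc <- 0
    ki <- 0L
    for (s in seq_len(n_steps)) {
      xp <- x + stats::rnorm(m, 0, prop_sd)
      up <- u_bias(xp, c0)
      acc <- log(stats::runif(m)) < (u - up) / rt
      x[acc] <- xp[acc]
      u[acc] <- up[acc]
      n_acc <- n_acc + sum(acc)
      if (s > burn_in && (s - burn_in) %% thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- x
      }
    }
    rate <- n_acc / (n_steps * m)
    if (rate < 0.05) {
      stop("Metropolis acceptance rate ", sprintf("%.3f", rate),
           " below floor 0.05 in window ", w, " (center ", c0,
           " nm); the spec is pathological for this sampler")
    }
    samples[[w]] <- as.vector(kept)[seq_len(n_keep_total)]
  }
  umbrella_windows(ctr, k, samples, protocol$temperature)
}

#' Write umbrella windows as per-window XVG files (pull-distance dialect)
#'
#' One two-column file (time ps, distance nm) per window, named
#' `pullx_window_###.xvg`, plus a `windows_manifest.csv` with centers,
#' spring constant and temperature.
#'
#' @param uws an [umbrella_windows()] set.
#' @param dir output directory (created if needed).
#' @param dt nominal sampling interval (ps) for the time column.
#' @return Invisibly, the manifest path.
#' @export
write_umbrella_xvg <- function(uws, dir, dt = 1) {
  stopifnot(inherits(uws, "umbrella_windows"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(uws$centers))
  for (w in seq_along(uws$centers)) {
    x <- uws$samples[[w]]
    files[w] <- file.path(dir, sprintf("pullx_window_%03d.xvg", w))
    write_xvg(cbind(seq_along(x) * dt, x), files[w],
              title = "Pull COM distance",
              xlabel = "Time (ps)", ylabel = "Position (nm)",
              comments = sprintf("window %d center %.4f nm k %.1f", w,
                                 uws$centers[w], uws$spring_constant))
  }
  manifest <- file.path(dir, "windows_manifest.csv")
  utils::write.csv(data.frame(file = basename(files), center = uws$centers,
                              spring_constant = uws$spring_constant,
                              temperature = uws$temperature),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read umbrella windows from a manifest written by [write_umbrella_xvg()]
#'
#' @param manifest path to `windows_manifest.csv`.
#' @return An [umbrella_windows()] set.
#' @export
read_umbrella_xvg <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  samples <- lapply(mf$file, function(f) read_xvg(file.path(dir, f))[[2]])
  umbrella_windows(mf$center, mf$spring_constant[1], samples,
                   mf$temperature[1])
}
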