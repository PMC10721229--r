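# Synthetic scattering data: Guinier-regime SANS curves with multiplicative
# Gaussian noise (count-statistics character) and linear SLS Debye-plot
# series with additive noise (instrument character).

#' Generate a Guinier-regime SANS curve
#'
#' `I(q) = i0 * exp(-q^2 rg^2 / 3) * (1 + eps)` with `eps ~ N(0, noise_sd)`.
#' The q grid spans `0.1 / rg` to `2.5 / rg`, i.e. well below and above the
#' Guinier limit `1.3 / rg`. Draws that would leave a non-positive intensity
#' are resampled (never clipped), so the noise is slightly truncated at
#' large `noise_sd`; at the default 1 percent level the truncation is
#' negligible.
#'
#' @param rg ground-truth radius of gyration (nm).
#' @param i0 forward intensity `I(0)`.
#' @param noise_sd relative noise standard deviation (0 = noiseless).
#' @param n_points number of q points.
#' @param seed integer RNG seed.
#' @return Object of class `"scattering_curve"`: a data.frame with columns
#'   `q` (1/nm), `I`, `sigma`; attributes `rg_true`, `i0_true`.
#' @export
gen_sans_curve <- function(rg, i0 = 100, noise_sd = 0.01, n_points = 80L,
                           seed = 1L) {
  if (rg <= 0) stop("rg must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_points < 5L) stop("need at least 5 q points")
  set.seed(as.integer(seed))
  q <- seq(0.1 / rg, 2.5 / rg, length.out = n_points)
  i_true <- i0 * exp(-q^2 * rg^2 / 3)
  if (noise_sd > 0) {
    eps <- stats::rnorm(n_points, 0, noise_sd)
    bad <- which(eps <= -1)
    while (length(bad)) {        # resample non-positive intensities
      eps[bad] <- stats::rnorm(length(bad), 0, noise_sd)
      bad <- bad[eps[bad] <= -1]
    }
    i_obs <- i_true * (1 + eps)
  } else {
    i_obs <- i_true
  }
  out <- data.frame(q = q, I = i_obs, sigma = noise_sd * i_true)
  attr(out, "rg_true") <- rg
  attr(out, "i0_true") <- i0
  class(out) <- c("scattering_curve", "data.frame")
  out
}

#' Generate a static light scattering concentration series
#'
#' `KC/R_theta = 1/mw + 2 * b22 * C + noise`, with `C` converted from the
#' mg/mL interface unit to g/mL internally so `b22` carries the
#' conventional mol mL / g^2 units. Noise is additive Gaussian on
#' `KC/R_theta` with absolute standard deviation `noise_sd` (units mol/g).
#'
#' @param mw ground-truth molecular weight (g/mol).
#' @param b22 ground-truth second virial coefficient (mol mL / g^2).
#' @param conc_mg_ml concentration grid (mg/mL), >= 3 positive values.
#' @param noise_sd additive noise sd on KC/R (mol/g); 0 = noiseless.
#' @param seed integer RNG seed.
#' @return Object of class `"sls_series"`: data.frame with `conc_mg_ml` and
#'   `kc_over_r` (mol/g); attributes `mw_true`, `b22_true`.
#' @export
gen_sls_series <- function(mw, b22, conc_mg_ml = seq(1, 8, by = 1),
                           noise_sd = 0, seed = 1L) {
  if (mw <= 0) stop("mw must be > 0")
  conc_mg_ml <- as.numeric(conc_mg_ml)
  if (length(conc_mg_ml) < 3L || any(conc_mg_ml <= 0)) {
    stop("need at least 3 positive concentrations")
  }
  set.seed(as.integer(seed))
  c_g_ml <- conc_mg_ml / 1000
  kc <- 1 / mw + 2 * b22 * c_g_ml
  if (noise_sd > 0) kc <- kc + stats::rnorm(length(kc), 0, noise_sd)
  out <- data.frame(conc_mg_ml = conc_mg_ml, kc_over_r = kc)
  attr(out, "mw_true") <- mw
  attr(out, "b22_true") <- b22
  class(out) <- c("sls_series", "data.frame")
  out
}
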