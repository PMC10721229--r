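# Experimental-side estimators: Guinier analysis of small-angle scattering
# curves (ln I vs q^2 linear fit restricted self-consistently to
# q * Rg <= criterion) and the Debye-plot regression of a static light
# scattering concentration series (intercept 1/Mw, slope 2 * B22).

#' Construct a scattering curve object
#'
#' @param q momentum transfer (1/nm), strictly increasing and positive.
#' @param I intensities (> 0 where fitted).
#' @param sigma optional intensity uncertainties (same length).
#' @return Object of class `"scattering_curve"` (a data.frame).
#' @export
scattering_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q)
  I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I lengths differ")
  if (any(q <= 0) || is.unsorted(q, strictly = TRUE)) {
    stop("q must be positive and strictly increasing")
  }
  out <- data.frame(q = q, I = I,
                    sigma = if (is.null(sigma)) NA_real_ else as.numeric(sigma))
  class(out) <- c("scattering_curve", "data.frame")
  out
}

#' Momentum transfer from wavelength and scattering angle
#'
#' `q = (4 pi / lambda) sin(theta)`.
#'
#' @param lambda wavelength (nm).
#' @param theta scattering half-angle (radians), in `(0, pi/2)`.
#' @return q in 1/nm.
#' @export
q_from_angle <- function(lambda, theta) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (any(theta <= 0) || any(theta >= pi / 2)) {
    stop("theta must lie in (0, pi/2)")
  }
  (4 * pi / lambda) * sin(theta)
}

#' Guinier fit: radius of gyration from a small-angle scattering curve
#'
#' Fits `ln I = ln I0 - (Rg^2 / 3) q^2` iteratively: the initial point set
#' is everything below the 10th percentile of q; after each fit the limit
#' is recomputed as `q_max = criterion / Rg` and the fit repeated until the
#' point set is stable (at most `max_iter` rounds). When `sigma` is present
#' the fit is weighted by `(I / sigma)^2`, the delta-method weight for
#' `ln I`.
#'
#' @param curve a `"scattering_curve"` (or data.frame with `q`, `I`,
#'   optional `sigma`).
#' @param criterion the Guinier-region bound on `q * Rg`; default 1.3.
#' @param max_iter maximum refit rounds; an oscillating point set is an
#'   error reporting both candidates.
#' @return Object of class `"guinier_fit"`: list with `rg` (nm), `i0`,
#'   `slope` (= -rg^2/3), `fit_range` (q min/max used), `r_squared`,
#'   `n_points`, `criterion`.
#' @export
guinier_fit <- function(curve, criterion = 1.3, max_iter = 20L) {
  q <- curve$q
  I <- curve$I
  sigma <- if (!is.null(curve$sigma)) curve$sigma else rep(NA_real_, length(q))
  use_all <- I > 0
  if (sum(use_all) < 5L) stop("need at least 5 positive-intensity points")
  wts <- ifelse(is.finite(sigma) & sigma > 0, (I / sigma)^2, 1)

  fit_set <- function(sel) {
    x <- q[sel]^2
    y <- log(I[sel])
    stats::lm(y ~ x, weights = wts[sel])
  }
  # initial set: lowest-q decile, widened progressively if noise leaves it
  # without a negative slope (a narrow low-q window can be noise-dominated)
  sel <- NULL
  for (pct in c(0.10, 0.25, 0.50, 1.00)) {
    cand <- use_all & q <= stats::quantile(q, pct)
    if (sum(cand) < 5L) next
    sl <- unname(stats::coef(fit_set(cand))[2])
    if (is.finite(sl) && sl < 0) { sel <- cand; break }
  }
  if (is.null(sel)) {
    stop("non-negative Guinier slope: the curve shows no Guinier decay")
  }
  prev_sets <- list()
  for (it in seq_len(max_iter)) {
    if (sum(sel) < 5L) stop("fewer than 5 points below the Guinier limit")
    fit <- fit_set(sel)
    slope <- unname(stats::coef(fit)[2])
    if (slope >= 0) {
      stop("non-negative Guinier slope: the curve shows no Guinier decay")
    }
    rg <- sqrt(-3 * slope)
    sel_new <- use_all & q <= criterion / rg
    if (identical(sel_new, sel)) break
    key <- paste(which(sel_new), collapse = ",")
    if (key %in% prev_sets) {
      # two-state cycle from a single point sitting on the limit: resolve
      # deterministically to the smaller (conservative) set, which still
      # satisfies q_max * Rg <= criterion; anything wider is a real failure
      if (identical(key, prev_sets[[length(prev_sets)]]) &&
          abs(sum(sel_new) - sum(sel)) <= 1L) {
        sel <- sel & sel_new
        fit <- fit_set(sel)
        slope <- unname(stats::coef(fit)[2])
        rg <- sqrt(-3 * slope)
        break
      }
      stop("Guinier point set oscillates between {",
           paste(which(sel), collapse = ","), "} and {",
           paste(which(sel_new), collapse = ","),
           "}; data have no stable Guinier regime")
    }
    prev_sets <- c(prev_sets, paste(which(sel), collapse = ","))
    sel <- sel_new
    if (it == max_iter) stop("Guinier point set did not stabilise in ",
                             max_iter, " iterations")
  }
  i0 <- exp(unname(stats::coef(fit)[1]))
  res <- stats::residuals(fit)
  y <- log(I[sel])
  ss_tot <- sum(wts[sel] * (y - stats::weighted.mean(y, wts[sel]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(wts[sel] * res^2) / ss_tot else 1
  structure(list(rg = rg, i0 = i0, slope = slope,
                 fit_range = range(q[sel]), r_squared = r2,
                 n_points = sum(sel), criterion = criterion),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.4f nm, I(0) = %.4g (%d points, q in %.3f-%.3f 1/nm)\n",
    x$rg, x$i0, x$n_points, x$fit_range[1], x$fit_range[2]))
  cat(sprintf("  q_max * Rg = %.3f (criterion %.2f), R^2 = %.5f\n",
              x$fit_range[2] * x$rg, x$criterion, x$r_squared))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) c(i0 = object$i0, rg = object$rg)

#' Construct a static light scattering series
#'
#' @param conc_mg_ml concentrations (mg/mL), >= 3 positive values.
#' @param kc_over_r `KC/R_theta` values (mol/g).
#' @return Object of class `"sls_series"` (a data.frame).
#' @export
sls_series <- function(conc_mg_ml, kc_over_r) {
  conc_mg_ml <- as.numeric(conc_mg_ml)
  if (length(conc_mg_ml) < 3L || any(conc_mg_ml <= 0)) {
    stop("need at least 3 positive concentrations")
  }
  if (length(kc_over_r) != length(conc_mg_ml)) stop("length mismatch")
  out <- data.frame(conc_mg_ml = conc_mg_ml,
                    kc_over_r = as.numeric(kc_over_r))
  class(out) <- c("sls_series", "data.frame")
  out
}

#' Optical constant K for static light scattering
#'
#' Standard Rayleigh form `K = 4 pi^2 n0^2 (dn/dC)^2 / (N_A lambda^4)`.
#' Users who already have `KC/R_theta` never need this.
#'
#' @param lambda wavelength (nm); default 633 (He-Ne).
#' @param dndc refractive-index increment (mL/g); default 0.185, typical
#'   for IgG-class proteins.
#' @param n0 solvent refractive index; default 1.33 (water).
#' @return K in mol cm^2 / g^2 (with `R_theta` in 1/cm, `KC/R_theta` is
#'   mol/g for C in g/mL).
#' @export
sls_optical_constant <- function(lambda = 633, dndc = 0.185, n0 = 1.33) {
  lambda_cm <- lambda * 1e-7
  4 * pi^2 * n0^2 * dndc^2 / (phys_constants$N_A * lambda_cm^4)
}

#' Debye-plot regression of an SLS concentration series
#'
#' Ordinary least squares of `KC/R_theta` on concentration (internally
#' g/mL): the intercept is `1/Mw` and the slope is `2 * B22`.
#'
#' @param series an `"sls_series"` (or data.frame with `conc_mg_ml`,
#'   `kc_over_r`).
#' @return Object of class `"debye_plot_fit"`: list with `b22`
#'   (mol mL / g^2), `mw` (g/mol), `slope_se`, `intercept_se`,
#'   `n_points`.
#' @export
sls_debye_fit <- function(series) {
  c_g_ml <- series$conc_mg_ml / 1000
  y <- series$kc_over_r
  if (length(unique(c_g_ml)) < 2L) {
    stop("rank-deficient design: need at least two distinct concentrations")
  }
  if (length(y) < 3L) stop("need at least 3 points")
  fit <- stats::lm(y ~ c_g_ml)
  cf <- stats::coef(fit)
  if (cf[1] <= 0) {
    stop("negative or zero Debye-plot intercept (unphysical apparent ",
         "molecular weight); check instrument calibration")
  }
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  structure(list(b22 = unname(cf[2]) / 2, mw = 1 / unname(cf[1]),
                 slope = unname(cf[2]), slope_se = unname(se[2]) ,
                 intercept_se = unname(se[1]), n_points = length(y)),
            class = "debye_plot_fit")
}

#' @export
print.debye_plot_fit <- function(x, ...) {
  cat(sprintf("Debye plot: Mw = %.0f g/mol, B22 = %.4e mol mL / g^2\n",
              x$mw, x$b22))
  cat(sprintf("  slope = %.4e +/- %.1e (2 x B22), %d points\n",
              x$slope, x$slope_se, x$n_points))
  invisible(x)
}

#' @export
coef.debye_plot_fit <- function(object, ...) {
  c(mw = object$mw, b22 = object$b22)
}
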