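# Synthetic ionic double layer: ion positions around a central "protein"
# drawn so that the ensemble-mean net charge beyond the surface decays as
# Q_protein * exp(-r / zeta). The generator is statistical, not physical: it
# samples radii by inverse CDF instead of solving electrostatics, which makes
# the downstream exponential-fit recovery test well-posed.

#' Specify a synthetic ion cloud
#'
#' @param protein_charge signed integer protein charge (e); e.g. +11 for a
#'   Fab-like fragment, +2 for Fc-like.
#' @param bulk_concentration nominal salt concentration (mol/L); metadata
#'   only (the ion count is set by `n_ion_pairs`).
#' @param target_zeta screening length (nm), > 0.
#' @param box_edge cubic box edge (nm); must exceed `6 * target_zeta` so the
#'   exponential has decayed at the half-box.
#' @param n_ion_pairs number of neutral cation/anion pairs; counter-ions in
#'   excess of the pairs (exactly `|protein_charge|` of them) are added on
#'   top, so total charge is zero in every frame.
#' @param seed integer RNG seed.
#' @return Object of class `"ion_cloud_spec"`.
#' @export
ion_cloud_spec <- function(protein_charge, bulk_concentration = 0.15,
                           target_zeta = 0.79, box_edge = 12,
                           n_ion_pairs = 148L, seed = 1L) {
  protein_charge <- as.integer(protein_charge)
  if (target_zeta <= 0) stop("target_zeta must be > 0")
  if (box_edge <= 6 * target_zeta) {
    stop("box_edge must exceed 6 * target_zeta (", 6 * target_zeta,
         " nm) so the screened charge decays within the half-box")
  }
  if (n_ion_pairs < 0L) stop("n_ion_pairs must be >= 0")
  structure(list(protein_charge = protein_charge,
                 bulk_concentration = bulk_concentration,
                 target_zeta = target_zeta, box_edge = box_edge,
                 n_ion_pairs = as.integer(n_ion_pairs),
                 seed = as.integer(seed)),
            class = "ion_cloud_spec")
}

#' Generate frames of the synthetic ion cloud
#'
#' A single massive central atom plays the protein. In each frame,
#' `n_ion_pairs` cations and anions are placed uniformly in the sphere of
#' radius `box_edge / 2` around it (these cancel in the net charge), and
#' `|protein_charge|` excess counter-ions are placed with radial density
#' proportional to `exp(-r / target_zeta)` (inverse-CDF sampling on
#' `[0, box_edge / 2]`). The ensemble-mean net charge within `r` of the
#' protein is therefore `protein_charge * exp(-r / target_zeta)` up to the
#' (negligible) truncation of the exponential, while every single frame
#' conserves total charge exactly.
#'
#' @param spec an [ion_cloud_spec()].
#' @param n_frames number of independent frames.
#' @return A [trajectory()]; topology species are `"protein"`, `"cation"`,
#'   `"anion"` with charges `protein_charge`, +1, -1.
#' @export
gen_ion_cloud <- function(spec, n_frames = 100L) {
  stopifnot(inherits(spec, "ion_cloud_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(spec$seed)

  q <- spec$protein_charge
  n_exc <- abs(q)
  n_cat <- spec$n_ion_pairs + if (q < 0) n_exc else 0L
  n_ani <- spec$n_ion_pairs + if (q > 0) n_exc else 0L
  r_max <- spec$box_edge / 2
  # density feasibility: the excess profile is a proper density by
  # construction; the pairs must fit the box at (roughly) bulk density
  v_nm3 <- (4 / 3) * pi * r_max^3
  if ((n_cat + n_ani) / v_nm3 > 50) {
    stop("infeasible ion cloud: requested ion count exceeds what the box ",
         "accommodates at liquid-like density")
  }

  zeta <- spec$target_zeta
  trunc_mass <- 1 - exp(-r_max / zeta)
  sample_excess_r <- function(n) -zeta * log(1 - stats::runif(n) * trunc_mass)
  sample_bulk_r <- function(n) r_max * stats::runif(n)^(1 / 3)
  rand_dir <- function(n) {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    cbind(rho * cos(phi), rho * sin(phi), z)
  }

  n_atoms <- 1L + n_cat + n_ani
  top <- topology(
    mass = c(50000, rep(22.99, n_cat), rep(35.45, n_ani)),
    species = c("protein", rep("cation", n_cat), rep("anion", n_ani)),
    charge = c(q, rep(1, n_cat), rep(-1, n_ani)),
    name = c("PRO", rep("NA", n_cat), rep("CL", n_ani)),
    resid = seq_len(n_atoms))

  centre <- rep(spec$box_edge / 2, 3)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    r_cat <- sample_bulk_r(spec$n_ion_pairs)
    r_ani <- sample_bulk_r(spec$n_ion_pairs)
    r_exc <- sample_excess_r(n_exc)
    if (q > 0) {
      r_ani <- c(r_ani, r_exc)
    } else if (q < 0) {
      r_cat <- c(r_cat, r_exc)
    }
    rr <- c(0, r_cat, r_ani)
    co <- rand_dir(n_atoms) * rr
    co <- sweep(co, 2, centre, "+")
    co[1, ] <- centre
    frames[[f]] <- list(coords = co, box = rep(spec$box_edge, 3),
                        time = f - 1)
  }
  trajectory(top, frames)
}
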