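# Synthetic ellipsoidal protein: a bead shell standing in for a Fab/Fc-like
# body. Frames are rigid rotations + translations with an optional isotropic
# "breathing" scale fluctuation, so every structural estimator downstream has
# an exact ground truth.

#' Specify a synthetic ellipsoidal bead protein
#'
#' The protein is a shell of beads on an ellipsoid surface. Six marker beads
#' sit at the axis tips (+/- each semi-axis) and carry the `LA`/`W`/`H`
#' marker labels used by [axis_dimensions()], so the true dimensions are
#' exactly twice the semi-axes.
#'
#' @param semi_axes three strictly positive semi-axis lengths (nm), given in
#'   the anatomical order long-axis, width, height.
#' @param n_beads total bead count (>= 6; the first six placements are the
#'   axis-tip markers unless `marker_bead_ids` says otherwise).
#' @param bead_mass mass per bead (g/mol).
#' @param breathing_amplitude relative isotropic scale fluctuation in
#'   `[0, 0.5)`; each frame is scaled by `1 + breathing_amplitude * u` with
#'   `u` uniform on `[-1, 1]`.
#' @param marker_bead_ids six bead indices receiving the marker labels, in
#'   the order +LA, -LA, +W, -W, +H, -H.
#' @param seed integer RNG seed.
#' @return Object of class `"ellipsoid_protein_spec"`.
#' @export
ellipsoid_protein_spec <- function(semi_axes, n_beads = 200L, bead_mass = 110,
                                   breathing_amplitude = 0,
                                   marker_bead_ids = 1:6, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("semi_axes must be three strictly positive lengths (nm)")
  }
  if (breathing_amplitude < 0 || breathing_amplitude >= 0.5) {
    stop("breathing_amplitude must lie in [0, 0.5)")
  }
  if (n_beads < 6L) stop("n_beads must be at least 6 (cannot place markers)")
  marker_bead_ids <- as.integer(marker_bead_ids)
  if (length(marker_bead_ids) != 6L || anyDuplicated(marker_bead_ids) ||
      any(marker_bead_ids < 1L) || any(marker_bead_ids > n_beads)) {
    stop("marker_bead_ids must be six distinct indices in 1..n_beads")
  }
  structure(list(semi_axes = semi_axes, n_beads = as.integer(n_beads),
                 bead_mass = bead_mass,
                 breathing_amplitude = breathing_amplitude,
                 marker_bead_ids = marker_bead_ids, seed = as.integer(seed)),
            class = "ellipsoid_protein_spec")
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# uniform random rotation matrix (via random unit quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a rigid-plus-breathing trajectory of the bead ellipsoid
#'
#' Each frame applies an independent uniform random rotation, a random
#' translation inside the central half of the box, and an isotropic scale
#' factor `1 + breathing_amplitude * u`, `u ~ U[-1, 1]`. Internal distances
#' are otherwise preserved, so with zero breathing every frame has identical
#' radius of gyration and axis dimensions.
#'
#' @param spec an [ellipsoid_protein_spec()].
#' @param n_frames number of frames (>= 1).
#' @param box_edge cubic box edge (nm); default four times the longest axis.
#' @return A [trajectory()] whose topology carries bead masses and the six
#'   axis markers.
#' @export
gen_protein_trajectory <- function(spec, n_frames, box_edge = NULL) {
  stopifnot(inherits(spec, "ellipsoid_protein_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (is.null(box_edge)) box_edge <- 8 * max(spec$semi_axes)
  set.seed(spec$seed)

  a <- spec$semi_axes
  tips <- rbind(c(a[1], 0, 0), c(-a[1], 0, 0),
                c(0, a[2], 0), c(0, -a[2], 0),
                c(0, 0, a[3]), c(0, 0, -a[3]))
  n_rest <- spec$n_beads - 6L
  base <- matrix(0, spec$n_beads, 3)
  base[spec$marker_bead_ids, ] <- tips
  if (n_rest > 0L) {
    # reflection-symmetrised shell: each lattice point appears with the four
    # sign patterns (+,+,+), (-,-,+), (-,+,-), (+,-,-), cancelling all
    # off-diagonal second moments so the gyration tensor is exactly diagonal
    # in the body frame and the principal axes coincide with the semi-axes
    n_quad <- n_rest %/% 4L
    shell <- NULL
    if (n_quad > 0L) {
      pts <- fibonacci_sphere(n_quad)
      signs <- rbind(c(1, 1, 1), c(-1, -1, 1), c(-1, 1, -1), c(1, -1, -1))
      shell <- do.call(rbind, lapply(1:4, function(s)
        sweep(pts, 2, signs[s, ], "*")))
    }
    n_left <- n_rest - 4L * n_quad
    if (n_left > 0L) {
      # leftovers sit on the coordinate axes, preserving the diagonal form
      axis_pts <- rbind(c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5))
      shell <- rbind(shell, axis_pts[seq_len(n_left), , drop = FALSE])
    }
    shell <- sweep(shell, 2, a, "*")
    base[setdiff(seq_len(spec$n_beads), spec$marker_bead_ids), ] <- shell
  }

  marker <- rep(NA_character_, spec$n_beads)
  marker[spec$marker_bead_ids] <- c("LA", "LA", "W", "W", "H", "H")
  top <- topology(mass = rep(spec$bead_mass, spec$n_beads),
                  species = "protein", name = "BEA", resname = "ELL",
                  resid = seq_len(spec$n_beads), marker = marker)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    rot <- random_rotation()
    s <- 1 + spec$breathing_amplitude * stats::runif(1, -1, 1)
    shift <- box_edge * (0.5 + stats::runif(3, -0.1, 0.1))
    co <- s * (base %*% t(rot))
    co <- sweep(co, 2, shift, "+")
    frames[[f]] <- list(coords = co, box = rep(box_edge, 3), time = f - 1)
  }
  trajectory(top, frames)
}
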