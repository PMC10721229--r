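# Shrake-Rupley solvent-accessible surface area. Each atom's sphere is
# inflated by the probe radius and covered with a deterministic Fibonacci
# point lattice; the exposed fraction times the inflated-sphere area is the
# atom's contribution. Neighbour search uses a grid cell list.

#' Bondi van der Waals radii (nm)
#'
#' Element-keyed radii used by [sasa()] when per-atom radii are not given.
#' The table is deliberately small and explicit; unknown elements are an
#' error, never silently defaulted.
#'
#' @export
bondi_radii <- stats::setNames(
  c(0.120, 0.170, 0.155, 0.152, 0.180, 0.180, 0.147, 0.175, 0.185, 0.198,
    0.227, 0.275),
  c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "NA", "K"))

# cell list: returns for each atom the indices of atoms in its own and
# neighbouring cells (cheaper than the full distance matrix for large n)
cell_neighbours <- function(coords, cutoff) {
  n <- nrow(coords)
  lo <- apply(coords, 2, min)
  cell <- pmax(cutoff, 1e-6)
  idx <- floor(sweep(coords, 2, lo, "-") / cell)
  key <- idx[, 1] + 1e4 * idx[, 2] + 1e8 * idx[, 3]
  buckets <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, size = length(buckets))
  for (b in names(buckets)) assign(b, buckets[[b]], envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  function(i) {
    ks <- (idx[i, 1] + offs[, 1]) + 1e4 * (idx[i, 2] + offs[, 2]) +
      1e8 * (idx[i, 3] + offs[, 3])
    out <- unlist(lapply(as.character(ks), function(k) {
      if (exists(k, envir = lookup, inherits = FALSE)) {
        get(k, envir = lookup, inherits = FALSE)
      }
    }), use.names = FALSE)
    out[out != i]
  }
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param traj a [trajectory()] (all frames are evaluated) or a single
#'   frame list with `coords`.
#' @param selection atom ids whose SASA is summed; default all atoms.
#'   Atoms outside the selection still occlude.
#' @param probe_radius probe (solvent) radius in nm; default 0.14 (water).
#' @param n_sphere_points surface points per atom; default 960.
#' @param radii per-atom radii (nm): a single number, a vector over all
#'   atoms, or `NULL` to look up `topology$element` in `radii_table`.
#' @param radii_table element-keyed radius table; default [bondi_radii].
#' @return Object of class `"sasa_result"`: list with `sasa` (nm^2 per
#'   frame), `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(traj, selection = NULL, probe_radius = 0.14,
                 n_sphere_points = 960L, radii = NULL,
                 radii_table = bondi_radii) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  single <- !inherits(traj, "trajectory")
  if (single) {
    frames <- list(traj)
    top <- NULL
    n_atoms <- nrow(traj$coords)
  } else {
    frames <- traj$frames
    top <- traj$topology
    n_atoms <- nrow(top)
  }
  if (is.null(selection)) selection <- seq_len(n_atoms)
  if (is.null(radii)) {
    if (is.null(top) || all(is.na(top$element))) {
      stop("per-atom radii required: supply radii= or a topology with elements")
    }
    el <- toupper(top$element)
    unknown <- setdiff(unique(el), names(radii_table))
    unknown <- unknown[!is.na(unknown)]
    if (length(unknown)) {
      stop("no radius for element(s): ", paste(unknown, collapse = ", "))
    }
    radii <- unname(radii_table[el])
  }
  radii <- rep_len(as.numeric(radii), n_atoms)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all atomic radii must be finite and > 0")
  }
  rr <- radii + probe_radius
  pts <- fibonacci_sphere(as.integer(n_sphere_points))
  per_frame <- vapply(frames, function(fr) {
    co <- fr$coords
    nb_of <- cell_neighbours(co, 2 * max(rr))
    total <- 0
    for (i in selection) {
      nb <- nb_of(i)
      if (length(nb)) {
        d2 <- (co[nb, 1] - co[i, 1])^2 + (co[nb, 2] - co[i, 2])^2 +
          (co[nb, 3] - co[i, 3])^2
        nb <- nb[d2 < (rr[i] + rr[nb])^2]
      }
      sp <- pts * rr[i]
      sp <- sweep(sp, 2, co[i, ], "+")
      exposed <- rep(TRUE, nrow(sp))
      for (j in nb) {
        if (!any(exposed)) break
        e <- which(exposed)
        d2 <- (sp[e, 1] - co[j, 1])^2 + (sp[e, 2] - co[j, 2])^2 +
          (sp[e, 3] - co[j, 3])^2
        exposed[e[d2 < rr[j]^2]] <- FALSE
      }
      total <- total + mean(exposed) * 4 * pi * rr[i]^2
    }
    total
  }, numeric(1))
  structure(list(sasa = per_frame, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "SASA: %d frame(s), mean %.4f nm^2 (probe %.3f nm, %d points/atom)\n",
    length(x$sasa), mean(x$sasa), x$probe_radius, x$n_sphere_points))
  invisible(x)
}
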