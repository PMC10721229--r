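# Residence (survival) statistics of species in the solvation shell.
# h_i(t) = 1 when species atom i lies within `cutoff` of the protein
# surface at frame t. Two standard estimators are provided and labelled:
#   intermittent: P(t) = <h(t0) h(t0+t)> / <h(t0)>
#   continuous:   P(t) = <h(t0) * prod_{s in [t0, t0+t]} h(s)> / <h(t0)>
# both averaged over all time origins and atoms.

#' Survival probability of species within a cutoff of the protein surface
#'
#' @param traj a [trajectory()] with uniformly spaced frames (>= 2).
#' @param protein_selection atom ids defining the surface.
#' @param species_selection atom ids whose residence is followed.
#' @param cutoff shell cutoff distance (nm); default 0.35.
#' @param definition `"intermittent"` (default) or `"continuous"`.
#' @param max_lag largest lag in frames; default `n_frames - 1`.
#' @return Object of class `"survival_curve"`: list with `lag` (ps), `p`
#'   in `[0, 1]` with `p[lag = 0] = 1`, `cutoff`, `definition`.
#' @export
survival_probability <- function(traj, protein_selection, species_selection,
                                 cutoff = 0.35,
                                 definition = c("intermittent", "continuous"),
                                 max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  definition <- match.arg(definition)
  nf <- length(traj$frames)
  if (nf < 2L) stop("need at least 2 frames")
  tms <- vapply(traj$frames, `[[`, numeric(1), "time")
  dts <- diff(tms)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts), 1))) {
    stop("frames must be uniformly spaced in time")
  }
  if (is.null(max_lag)) max_lag <- nf - 1L
  max_lag <- min(as.integer(max_lag), nf - 1L)

  h <- vapply(traj$frames, function(fr) {
    assert_orthorhombic(fr$box)
    min_surface_distances(fr$coords, protein_selection, species_selection,
                          fr$box) <= cutoff
  }, logical(length(species_selection)))
  h <- matrix(h, nrow = length(species_selection))   # atoms x frames
  if (!any(h)) stop("no species atom is ever within the cutoff")

  p <- numeric(max_lag + 1L)
  p[1] <- 1
  if (definition == "intermittent") {
    for (lag in seq_len(max_lag)) {
      orig <- h[, 1:(nf - lag), drop = FALSE]
      late <- h[, (1 + lag):nf, drop = FALSE]
      p[lag + 1L] <- sum(orig & late) / sum(orig)
    }
  } else {
    # running AND over the window [t0, t0+lag]
    run <- h
    for (lag in seq_len(max_lag)) {
      run <- run[, 1:(ncol(run) - 1L), drop = FALSE] &
        h[, (1 + lag):nf, drop = FALSE]
      p[lag + 1L] <- sum(run) / sum(h[, 1:(nf - lag), drop = FALSE])
    }
  }
  structure(list(lag = (0:max_lag) * dts[1], p = p, cutoff = cutoff,
                 definition = definition),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "Survival curve (%s, cutoff %.2f nm): %d lags, P(max lag) = %.3f\n",
    x$definition, x$cutoff, length(x$lag), x$p[length(x$p)]))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ...) {
  graphics::plot(x$lag, x$p, type = "l", ylim = c(0, 1),
                 xlab = "lag (ps)", ylab = "P(t)", ...)
  invisible(x)
}
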