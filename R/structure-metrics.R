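# Per-frame protein size and shape: mass-weighted radius of gyration, its
# distribution, and anatomical dimensions (long axis, width, height) via the
# gyration-tensor principal axes. Selections are assumed whole (unwrapped);
# no periodic imaging is applied across a selection.

#' Mass-weighted radius of gyration per frame
#'
#' `Rg^2 = sum_i m_i (r_i - R_com)^2 / sum_i m_i` over the selection, with
#' the mass-weighted centre of mass `R_com`.
#'
#' @param traj a [trajectory()].
#' @param selection atom ids (e.g. from [select_atoms()]); default all atoms.
#' @return Object of class `"rg_series"`: list with `rg` (nm, per frame),
#'   `time` (ps), `mean`, `sd`.
#' @export
radius_of_gyration <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(selection)) selection <- traj$topology$id
  if (!length(selection)) stop("selection is empty")
  m <- traj$topology$mass[selection]
  mt <- sum(m)
  if (!is.finite(mt) || mt <= 0) stop("zero or invalid total mass in selection")
  rg <- vapply(traj$frames, function(fr) {
    co <- fr$coords[selection, , drop = FALSE]
    cm <- colSums(co * m) / mt
    d2 <- (co[, 1] - cm[1])^2 + (co[, 2] - cm[2])^2 + (co[, 3] - cm[3])^2
    sqrt(sum(m * d2) / mt)
  }, numeric(1))
  structure(list(rg = rg,
                 time = vapply(traj$frames, `[[`, numeric(1), "time"),
                 mean = mean(rg), sd = stats::sd(rg)),
            class = "rg_series")
}

#' @export
print.rg_series <- function(x, ...) {
  cat(sprintf("Rg series: %d frames, mean %.4f nm, sd %.4f nm\n",
              length(x$rg), x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Probability distribution of the radius of gyration
#'
#' Density-normalised histogram of per-frame Rg. Multiple series (e.g.
#' independent trajectories) are pooled for the histogram; per-series means
#' are reported alongside.
#'
#' @param rg_series an `"rg_series"`, a list of them, or a numeric vector.
#' @param bin_width histogram bin width (nm), > 0. The 0.01 nm default
#'   resolves closely spaced conformational peaks.
#' @return Object of class `"rg_distribution"`: list with `breaks`, `mids`,
#'   `density` (integrates to 1), `mean`, `sd`, `series_means`.
#' @export
rg_distribution <- function(rg_series, bin_width = 0.01) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (inherits(rg_series, "rg_series")) rg_series <- list(rg_series)
  if (is.numeric(rg_series)) rg_series <- list(list(rg = rg_series))
  vals <- lapply(rg_series, function(s) if (is.list(s)) s$rg else s)
  pooled <- unlist(vals)
  if (length(pooled) < 2L) stop("need at least 2 frames")
  lo <- floor(min(pooled) / bin_width) * bin_width
  hi <- ceiling(max(pooled) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 counts = h$counts, mean = mean(pooled),
                 sd = stats::sd(pooled),
                 series_means = vapply(vals, mean, numeric(1))),
            class = "rg_distribution")
}

#' @export
plot.rg_distribution <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h",
                 xlab = "Rg (nm)", ylab = "probability density", ...)
  invisible(x)
}

# mass-weighted gyration tensor of a coordinate block
gyration_tensor <- function(coords, mass) {
  mt <- sum(mass)
  cm <- colSums(coords * mass) / mt
  d <- sweep(coords, 2, cm, "-")
  crossprod(d * sqrt(mass)) / mt
}

#' Anatomical dimensions (long axis, width, height) per frame
#'
#' Per frame, the eigenvectors of the mass-weighted gyration tensor of the
#' selection, sorted by descending eigenvalue, define the principal axes
#' PA1, PA2, PA3. For each of the three marker pairs (atom-id groups at the
#' opposite ends of an axis) the distance vector between the two groups'
#' centres of mass is projected on the pair's assigned axis (LA on PA1, W
#' on PA2, H on PA3) and the absolute component reported.
#'
#' Axes are ordered by eigenvalue in every frame (the anatomical
#' assignment). When two eigenvalues are nearly degenerate the order within
#' that pair is ambiguous; it is then tie-broken by maximal overlap with
#' the previous frame's axes, with a warning. Signs never matter since the
#' reported component is absolute.
#'
#' @param traj a [trajectory()].
#' @param selection atom ids used for the gyration tensor; default all
#'   protein atoms.
#' @param marker_pairs list of three elements named `LA`, `W`, `H`, each a
#'   list of two atom-id vectors (the opposing residue groups). Default:
#'   read the `marker` column of the topology.
#' @param degeneracy_tol relative eigenvalue gap below which a warning is
#'   issued.
#' @return Object of class `"dimension_result"`: list with per-frame `LA`,
#'   `W`, `H` (nm) and a `summary` data.frame (mean, sd).
#' @export
axis_dimensions <- function(traj, selection = NULL, marker_pairs = NULL,
                            degeneracy_tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  if (is.null(selection)) {
    selection <- top$id[top$species == "protein"]
    if (!length(selection)) selection <- top$id
  }
  if (is.null(marker_pairs)) {
    marker_pairs <- lapply(c(LA = "LA", W = "W", H = "H"), function(lab) {
      ids <- top$id[!is.na(top$marker) & top$marker == lab]
      if (length(ids) != 2L) {
        stop("topology must carry exactly two '", lab,
             "' markers, or marker_pairs must be supplied")
      }
      list(ids[1], ids[2])
    })
  }
  if (length(marker_pairs) != 3L) stop("need three marker pairs (LA, W, H)")
  if (is.null(names(marker_pairs))) names(marker_pairs) <- c("LA", "W", "H")
  m <- top$mass
  msel <- m[selection]
  nf <- length(traj$frames)
  out <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("LA", "W", "H")))
  axes_prev <- NULL
  warned <- FALSE
  for (f in seq_len(nf)) {
    co <- traj$frames[[f]]$coords
    gt <- gyration_tensor(co[selection, , drop = FALSE], msel)
    eg <- eigen(gt, symmetric = TRUE)   # eigenvalues descending
    axes <- eg$vectors
    gaps <- abs(diff(eg$values)) / max(eg$values)
    degen <- which(gaps < degeneracy_tol)
    if (length(degen)) {
      if (!warned) {
        warning("nearly degenerate gyration-tensor eigenvalues in frame ",
                f, "; axis assignment tie-broken by continuity with the ",
                "previous frame")
        warned <- TRUE
      }
      # swap within the ambiguous pair if the previous frame overlaps better
      if (!is.null(axes_prev)) {
        for (g in degen) {
          pair <- c(g, g + 1L)
          ov <- abs(crossprod(axes_prev[, pair], axes[, pair]))
          if (ov[1, 2] + ov[2, 1] > ov[1, 1] + ov[2, 2]) {
            axes[, pair] <- axes[, rev(pair)]
          }
        }
      }
    }
    axes_prev <- axes
    for (a in 1:3) {
      pr <- marker_pairs[[a]]
      c1 <- com(co, m, pr[[1]])
      c2 <- com(co, m, pr[[2]])
      out[f, a] <- abs(sum((c1 - c2) * axes[, a]))
    }
  }
  summ <- data.frame(axis = c("LA", "W", "H"),
                     mean = colMeans(out),
                     sd = apply(out, 2, stats::sd))
  structure(list(LA = out[, 1], W = out[, 2], H = out[, 3], summary = summ),
            class = "dimension_result")
}

#' @export
print.dimension_result <- function(x, ...) {
  cat("Protein dimensions over", length(x$LA), "frame(s):\n")
  s <- x$summary
  for (i in 1:3) {
    cat(sprintf("  %-2s: %.3f +/- %.3f nm\n", s$axis[i], s$mean[i],
                if (is.na(s$sd[i])) 0 else s$sd[i]))
  }
  invisible(x)
}
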