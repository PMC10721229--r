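# Weighted Histogram Analysis Method. Window histograms n_ij over a common
# grid are combined self-consistently:
#   p_j = (sum_i n_ij) / (sum_i N_i exp(f_i / RT) c_ij)
#   exp(-f_i / RT) = sum_j c_ij p_j,     c_ij = exp(-U_i(x_j) / RT)
# iterated until max |delta f_i| < tol. The bias factors c_ij are computed
# once; the default iteration then runs in linear space (safe because every
# window has c_ij = 1 at its own centre), with an optional fully
# log-sum-exp-stabilised path.

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' @param windows an [umbrella_windows()] set; adjacent windows must
#'   overlap (share at least one occupied histogram bin).
#' @param n_bins number of histogram bins over the sampled range
#'   (default 200).
#' @param tol convergence tolerance on the window free energies f_i
#'   (kJ/mol); default 1e-8.
#' @param max_iter iteration cap; non-convergence is an error, never a
#'   silent return.
#' @param method `"linear"` (default) or `"logsumexp"` (fully stabilised;
#'   same fixed point, slower).
#' @param n_boot Bayesian bootstrap replicates for per-bin uncertainties
#'   (0 disables). Each replicate re-weights samples within windows with
#'   Dirichlet(1) weights and re-solves WHAM.
#' @param reference `"last"` (default; zero at the largest sampled bin,
#'   where the profile has plateaued), `"plateau"` (zero mean over the last
#'   `plateau_width` nm of the sampled range, which is much less noisy than
#'   a single bin and is what downstream virial integration wants), or a
#'   numeric r (nm) naming the reference bin.
#' @param plateau_width width (nm) of the plateau-averaging region used
#'   when `reference = "plateau"`; default 0.5.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `"pmf_profile"`: list with `r` (bin centres,
#'   nm), `dg` (kJ/mol, reference bin exactly 0), `se` (bootstrap standard
#'   error per bin, NA if `n_boot = 0`), `f_windows`, `n_iter`,
#'   `temperature`.
#' @export
wham <- function(windows, n_bins = 200L, tol = 1e-8, max_iter = 1e5,
                 method = c("linear", "logsumexp"), n_boot = 0L,
                 reference = "last", plateau_width = 0.5, seed = 1L) {
  stopifnot(inherits(windows, "umbrella_windows"))
  method <- match.arg(method)
  rt <- rt_kj(windows$temperature)
  k <- windows$spring_constant
  ctr <- windows$centers
  all_x <- unlist(windows$samples)
  rng <- range(all_x)
  if (diff(rng) <= 0) stop("degenerate samples: zero range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2

  bin_of <- lapply(windows$samples, function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), n_bins)
  })
  counts <- t(vapply(bin_of, function(b) tabulate(b, n_bins),
                     numeric(n_bins)))           # windows x bins
  n_i <- rowSums(counts)

  # overlap check between adjacent windows
  occ <- counts > 0
  for (i in seq_len(nrow(occ) - 1L)) {
    if (!any(occ[i, ] & occ[i + 1L, ])) {
      stop("windows ", i, " and ", i + 1L, " (centers ", ctr[i], ", ",
           ctr[i + 1L], " nm) share no occupied bin; the ladder has a gap")
    }
  }

  bias <- 0.5 * k * outer(ctr, mids, "-")^2      # windows x bins, kJ/mol
  solve_wham <- function(cnt, f_init = NULL) {
    ni <- rowSums(cnt)
    mj <- colSums(cnt)
    f <- if (is.null(f_init)) numeric(length(ctr)) else f_init
    if (method == "linear") {
      cb <- exp(-bias / rt)
      for (it in seq_len(max_iter)) {
        denom <- colSums((ni * exp(f / rt)) * cb)
        p <- ifelse(mj > 0, mj / denom, 0)
        z <- as.vector(cb %*% p)
        f_new <- -rt * log(z)
        f_new <- f_new - f_new[1]
        delta <- max(abs(f_new - f))
        f <- f_new
        if (delta < tol) {
          return(list(p = p / sum(p), f = f, n_iter = it, converged = TRUE))
        }
      }
    } else {
      lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
      log_ni <- log(ni)
      for (it in seq_len(max_iter)) {
        log_denom <- apply((log_ni + f / rt) - bias / rt, 2, lse)
        log_p <- ifelse(mj > 0, log(mj) - log_denom, -Inf)
        f_new <- -rt * apply(sweep(-bias / rt, 2, log_p, "+"), 1, lse)
        f_new <- f_new - f_new[1]
        delta <- max(abs(f_new - f))
        f <- f_new
        if (delta < tol) {
          p <- exp(log_p - lse(log_p))
          return(list(p = p, f = f, n_iter = it, converged = TRUE))
        }
      }
    }
    stop("WHAM failed to converge in ", max_iter,
         " iterations (final max |delta f| = ", format(delta), " kJ/mol)")
  }

  sol <- solve_wham(counts)
  dg <- -rt * log(sol$p)
  dg[!is.finite(dg)] <- NA_real_

  plateau_bins <- NULL
  if (identical(reference, "plateau")) {
    plateau_bins <- which(is.finite(dg) &
                            mids >= max(mids[is.finite(dg)]) - plateau_width)
    if (length(plateau_bins) < 2L) stop("plateau region has fewer than 2 bins")
    shift_of <- function(g) mean(g[plateau_bins])
    ref_r <- mids[max(plateau_bins)]
  } else {
    ref_bin <- if (identical(reference, "last")) {
      max(which(is.finite(dg)))
    } else {
      which.min(abs(mids - as.numeric(reference)))
    }
    if (!is.finite(dg[ref_bin])) stop("reference bin was never sampled")
    shift_of <- function(g) g[ref_bin]
    ref_r <- mids[ref_bin]
  }
  dg <- dg - shift_of(dg)

  se <- rep(NA_real_, n_bins)
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    boot <- matrix(NA_real_, n_boot, n_bins)
    for (b in seq_len(n_boot)) {
      cnt_b <- t(vapply(bin_of, function(bi) {
        w <- stats::rexp(length(bi))
        w <- w * (length(bi) / sum(w))       # Dirichlet(1) x N weights
        wt <- numeric(n_bins)
        sums <- rowsum(w, bi)
        wt[as.integer(rownames(sums))] <- sums[, 1]
        wt
      }, numeric(n_bins)))
      sb <- solve_wham(cnt_b, f_init = sol$f)   # warm start
      dgb <- -rt * log(sb$p)
      boot[b, ] <- dgb - shift_of(dgb)
    }
    se <- apply(boot, 2, stats::sd)
  }

  structure(list(r = mids, dg = dg, se = se, f_windows = sol$f,
                 n_iter = sol$n_iter, temperature = windows$temperature,
                 reference_r = ref_r),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$dg)
  cat(sprintf(
    "PMF profile: %d bins on %.3f-%.3f nm, min %.2f kJ/mol at %.3f nm\n",
    length(x$r), min(x$r), max(x$r), min(x$dg[fin]),
    x$r[fin][which.min(x$dg[fin])]))
  cat(sprintf("  zero reference at r = %.3f nm; converged in %d iterations\n",
              x$reference_r, x$n_iter))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$r, x$dg, type = "l", xlab = "r (nm)",
                 ylab = expression(Delta * G * " (kJ/mol)"), ...)
  if (any(is.finite(x$se))) {
    graphics::arrows(x$r, x$dg - x$se, x$r, x$dg + x$se, length = 0.02,
                     angle = 90, code = 3, col = "grey60")
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
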