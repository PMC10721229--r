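# WHAM reconstruction: degenerate cases, recovery, invariances, and a
# cross-check against an independently coded textbook iteration.

# naive reference WHAM, written directly from the self-consistency
# equations with no reuse of package internals
naive_wham <- function(centers, k, samples, temperature, edges, tol = 1e-10,
                       max_iter = 2e5) {
  rt <- 1.380649e-23 * 6.02214076e23 / 1000 * temperature
  nb <- length(edges) - 1L
  mids <- (edges[-1] + edges[-(nb + 1L)]) / 2
  nw <- length(centers)
  n <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    h <- hist(samples[[i]], breaks = edges, plot = FALSE)
    n[i, ] <- h$counts
  }
  Ni <- rowSums(n)
  f <- rep(0, nw)
  bias <- matrix(0, nw, nb)
  for (i in seq_len(nw)) bias[i, ] <- 0.5 * k * (mids - centers[i])^2
  for (it in seq_len(max_iter)) {
    p <- numeric(nb)
    for (j in seq_len(nb)) {
      p[j] <- sum(n[, j]) / sum(Ni * exp((f - bias[, j]) / rt))
    }
    fn <- numeric(nw)
    for (i in seq_len(nw)) {
      fn[i] <- -rt * log(sum(p * exp(-bias[i, ] / rt)))
    }
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  dg <- -rt * log(p / sum(p))
  dg - dg[max(which(is.finite(dg)))]
}

test_that("a single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(131)
  rt <- rt_kj(300)
  # samples from exp(-dG/RT) with dG = harmonic bowl; draw directly
  x <- rnorm(20000, 5, sqrt(rt / 50))   # dG = 25 (x-5)^2 => sd = sqrt(RT/50)
  uws <- umbrella_windows(5, spring_constant = 1e-12, samples = list(x))
  pp <- wham(uws, n_bins = 60)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 61), plot = FALSE)
  ref <- -rt * log(h$counts / sum(h$counts))
  ref <- ref - ref[max(which(is.finite(ref)))]
  keep <- is.finite(pp$dg) & is.finite(ref)
  expect_lt(max(abs(pp$dg[keep] - ref[keep])), 1e-6)
})

test_that("a flat PMF is reconstructed flat within bootstrap error", {
  pmf <- analytic_pmf("flat", r_range = c(3, 8))
  prot <- umbrella_protocol(samples_per_window = 1500, seed = 141)
  uws <- gen_umbrella_windows(pmf, prot)
  pp <- wham(uws, n_bins = 100, n_boot = 20, seed = 141)
  fin <- is.finite(pp$dg)
  # flat to within a few bootstrap standard errors everywhere
  expect_lt(max(abs(pp$dg[fin]) / pmax(3 * pp$se[fin], 0.3)), 1)
  expect_equal(pp$dg[max(which(fin))], 0)   # reference bin exactly zero
})

test_that("linear and log-sum-exp iterations agree on a deep well", {
  pmf <- analytic_pmf("gaussian_well", well_depth = 20, well_center = 4,
                      well_width = 0.3, r_range = c(3, 6))
  prot <- umbrella_protocol(window_centers = seq(3.2, 5.8, by = 0.2),
                            samples_per_window = 800, seed = 151)
  uws <- gen_umbrella_windows(pmf, prot)
  p1 <- wham(uws, n_bins = 80, method = "linear")
  p2 <- wham(uws, n_bins = 80, method = "logsumexp")
  keep <- is.finite(p1$dg) & is.finite(p2$dg)
  expect_lt(max(abs(p1$dg[keep] - p2$dg[keep])), 1e-5)
})

test_that("WHAM matches an independently coded reference to < 0.05 kJ/mol", {
  pmf <- analytic_pmf("gaussian_well", well_depth = 8, well_center = 4.5,
                      well_width = 0.35, r_range = c(3.5, 5.5))
  prot <- umbrella_protocol(window_centers = seq(3.7, 5.3, by = 0.2),
                            samples_per_window = 600, seed = 161)
  uws <- gen_umbrella_windows(pmf, prot)
  all_x <- unlist(uws$samples)
  pp <- wham(uws, n_bins = 40, tol = 1e-10)
  edges <- seq(min(all_x), max(all_x), length.out = 41)
  ref <- naive_wham(uws$centers, uws$spring_constant, uws$samples, 300, edges)
  keep <- is.finite(pp$dg) & is.finite(ref)
  expect_lt(max(abs(pp$dg[keep] - ref[keep])), 0.05)
})

test_that("WHAM recovers a known well and is shift-equivariant", {
  pmf <- analytic_pmf("gaussian_well", well_depth = 12, well_center = 4.2,
                      well_width = 0.3, r_range = c(3, 7))
  prot <- umbrella_protocol(window_centers = seq(3, 7, by = 0.1),
                            samples_per_window = 4000, seed = 171)
  uws <- gen_umbrella_windows(pmf, prot)
  pp <- wham(uws, n_bins = 150)
  truth <- pmf$fun(pp$r) - pmf$fun(pp$reference_r)
  fin <- is.finite(pp$dg)
  expect_lt(max(abs(pp$dg[fin] - truth[fin])), 0.75)
  expect_lt(abs(min(pp$dg[fin]) - (-12)), 1)
  # shifting all centers and samples rigidly shifts the profile
  shift <- 1.7
  uws_s <- umbrella_windows(uws$centers + shift, uws$spring_constant,
                            lapply(uws$samples, `+`, shift))
  pp_s <- wham(uws_s, n_bins = 150)
  expect_equal(pp_s$r, pp$r + shift, tolerance = 1e-12)
  expect_equal(pp_s$dg, pp$dg, tolerance = 1e-8)
})

test_that("gapped ladders and non-convergence fail with clear errors", {
  set.seed(181)
  s1 <- rnorm(500, 3, 0.03)
  s2 <- rnorm(500, 6, 0.03)   # no overlap
  uws <- umbrella_windows(c(3, 6), 1000, list(s1, s2))
  expect_error(wham(uws, n_bins = 100), "share no occupied bin")
  s3 <- rnorm(500, 3.05, 0.05)
  uws2 <- umbrella_windows(c(3, 3.1), 1000, list(s1, s3))
  expect_error(wham(uws2, max_iter = 2), "failed to converge")
})

test_that("first-half vs full-sample profiles agree within bootstrap error", {
  pmf <- analytic_pmf("gaussian_well", well_depth = 10, well_center = 4,
                      well_width = 0.3, r_range = c(3, 6))
  prot <- umbrella_protocol(window_centers = seq(3.2, 5.8, by = 0.2),
                            samples_per_window = 3000, seed = 191)
  uws <- gen_umbrella_windows(pmf, prot)
  half <- umbrella_windows(uws$centers, uws$spring_constant,
                           lapply(uws$samples, function(x)
                             x[seq_len(length(x) %/% 2)]))
  pf <- wham(uws, n_bins = 60, n_boot = 20, seed = 191)
  ph <- wham(half, n_bins = 60)
  # compare on the shared grid by interpolation
  hi <- approx(ph$r, ph$dg, xout = pf$r)$y
  keep <- is.finite(pf$dg) & is.finite(hi) & is.finite(pf$se)
  expect_lt(stats::median(abs(pf$dg[keep] - hi[keep]) /
                            pmax(3 * pf$se[keep], 0.2)), 1)
})
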