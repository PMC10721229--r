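# Generators: determinism, ground-truth invariants, and sampling fidelity.

test_that("protein generator is deterministic and rigid under zero breathing", {
  spec <- ellipsoid_protein_spec(c(3.9, 2.875, 2.275), n_beads = 120,
                                 breathing_amplitude = 0, seed = 99)
  t1 <- gen_protein_trajectory(spec, 4)
  t2 <- gen_protein_trajectory(spec, 4)
  expect_identical(t1$frames, t2$frames)           # bitwise reproducible
  rg <- radius_of_gyration(t1)
  expect_equal(diff(range(rg$rg)), 0, tolerance = 1e-12)
  expect_error(
    gen_protein_trajectory(
      ellipsoid_protein_spec(c(1, 1, 1), n_beads = 5), 1),
    "at least 6")
})

test_that("marker beads give the crystal-structure dimensions on every frame", {
  spec <- ellipsoid_protein_spec(c(3.9, 2.875, 2.275), n_beads = 200,
                                 breathing_amplitude = 0, seed = 5)
  traj <- gen_protein_trajectory(spec, 6)
  d <- axis_dimensions(traj)
  expect_equal(d$LA, rep(7.8, 6), tolerance = 1e-9)
  expect_equal(d$W, rep(5.75, 6), tolerance = 1e-9)
  expect_equal(d$H, rep(4.55, 6), tolerance = 1e-9)
})

test_that("breathing scales Rg frame-by-frame within the stated amplitude", {
  spec <- ellipsoid_protein_spec(c(3, 2, 1.5), n_beads = 80,
                                 breathing_amplitude = 0.2, seed = 2)
  rg <- radius_of_gyration(gen_protein_trajectory(spec, 50))
  rg0 <- radius_of_gyration(gen_protein_trajectory(
    ellipsoid_protein_spec(c(3, 2, 1.5), n_beads = 80,
                           breathing_amplitude = 0, seed = 2), 1))$rg[1]
  expect_true(all(rg$rg >= rg0 * 0.8 - 1e-9 & rg$rg <= rg0 * 1.2 + 1e-9))
  expect_gt(diff(range(rg$rg)), 0)
})

test_that("ion cloud conserves charge exactly and carries the counterion excess", {
  spec <- ion_cloud_spec(protein_charge = 11, n_ion_pairs = 148, seed = 3)
  cl <- gen_ion_cloud(spec, n_frames = 3)
  top <- cl$topology
  expect_equal(sum(top$charge), 0)
  expect_equal(sum(top$species == "anion") - sum(top$species == "cation"), 11)
  # neutral system: no excess, Qnet flat at zero
  cl0 <- gen_ion_cloud(ion_cloud_spec(0, n_ion_pairs = 50, seed = 4),
                       n_frames = 40)
  pid <- select_atoms(cl0, species == "protein")
  rc <- surface_rdf(cl0, pid, select_atoms(cl0, species == "cation"),
                    bin_width = 0.05)
  ra <- surface_rdf(cl0, pid, select_atoms(cl0, species == "anion"),
                    bin_width = 0.05)
  qp <- net_charge_profile(rc, ra, 0)
  expect_lt(max(abs(qp$qnet)), 3)        # fluctuations only, mean 0
  expect_equal(qp$qnet[length(qp$qnet)], 0, tolerance = 1e-9)
})

test_that("excess counterion radii follow the truncated exponential law", {
  zeta <- 0.6
  spec <- ion_cloud_spec(protein_charge = 8, target_zeta = zeta,
                         box_edge = 10, n_ion_pairs = 0, seed = 8)
  cl <- gen_ion_cloud(spec, n_frames = 400)
  centre <- rep(5, 3)
  rr <- unlist(lapply(cl$frames, function(fr) {
    d <- sweep(fr$coords[-1, , drop = FALSE], 2, centre, "-")
    sqrt(rowSums(d^2))
  }))
  r_max <- 5
  cdf <- function(r) (1 - exp(-r / zeta)) / (1 - exp(-r_max / zeta))
  ks <- suppressWarnings(stats::ks.test(rr, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("umbrella sampling obeys equipartition and centring on a flat PMF", {
  pmf <- analytic_pmf("flat", r_range = c(2, 9))
  prot <- umbrella_protocol(window_centers = c(4, 5.5, 7),
                            spring_constant = 2000,
                            samples_per_window = 4000, seed = 6)
  uws <- gen_umbrella_windows(pmf, prot)
  rt <- rt_kj(300)
  for (w in 1:3) {
    x <- uws$samples[[w]]
    se <- sd(x) / sqrt(length(x) / 4)    # generous ess
    expect_lt(abs(mean(x) - prot$window_centers[w]), 3 * se)
    expect_lt(abs(var(x) - rt / 2000) / (rt / 2000), 0.10)
  }
  # determinism
  uws2 <- gen_umbrella_windows(pmf, prot)
  expect_identical(uws$samples, uws2$samples)
})

test_that("window samples match the analytic biased density (KS)", {
  pmf <- analytic_pmf("gaussian_well", well_depth = 10, well_center = 4,
                      well_width = 0.3, r_range = c(3, 8))
  k <- 1000
  c0 <- 4.1
  prot <- umbrella_protocol(window_centers = c0, spring_constant = k,
                            samples_per_window = 3000, seed = 12)
  uws <- gen_umbrella_windows(pmf, prot, thin = 20)
  rt <- rt_kj(300)
  grid <- seq(3, 8, length.out = 20001)
  dens <- exp(-(pmf$fun(grid) + 0.5 * k * (grid - c0)^2) / rt)
  cdf_vals <- cumsum(dens)
  cdf_vals <- cdf_vals / cdf_vals[length(cdf_vals)]
  cdf <- approxfun(grid, cdf_vals, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(uws$samples[[1]], cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("pathological umbrella specs fail with an acceptance-rate error", {
  # spring far too weak to confine the walker inside the PMF support:
  # almost every proposal lands outside and is rejected
  pmf <- analytic_pmf("flat", r_range = c(0, 10))
  expect_error(
    gen_umbrella_windows(
      pmf, umbrella_protocol(window_centers = 5, spring_constant = 1e-4,
                             samples_per_window = 200, seed = 1),
      burn_in = 10),
    "acceptance rate")
})

test_that("SANS generator inverts exactly at zero noise", {
  cv <- gen_sans_curve(rg = 2.5, i0 = 50, noise_sd = 0)
  # slope of ln I vs q^2 is -rg^2/3 by construction
  sl <- coef(lm(log(cv$I) ~ I(cv$q^2)))[2]
  expect_equal(unname(sl), -2.5^2 / 3, tolerance = 1e-12)
  gf <- guinier_fit(cv)
  expect_equal(gf$rg, 2.5, tolerance = 1e-10)
  # Guinier limit for the 2.65 nm fragment sits near 0.49 1/nm
  expect_equal(1.3 / 2.65, 0.4906, tolerance = 1e-3)
  # positivity after noise resampling
  cvn <- gen_sans_curve(rg = 2.5, i0 = 1, noise_sd = 0.5, seed = 3)
  expect_true(all(cvn$I > 0))
})

test_that("SLS generator encodes intercept 1/Mw and slope 2 B22", {
  ss <- gen_sls_series(mw = 49635, b22 = 0, noise_sd = 0)
  fit <- lm(kc_over_r ~ I(conc_mg_ml / 1000), data = ss)
  expect_equal(unname(coef(fit)[1]), 1 / 49635, tolerance = 1e-15)
  expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-12)
  ss2 <- gen_sls_series(mw = 49635, b22 = -7.77e-2, noise_sd = 0)
  expect_equal(sls_debye_fit(ss2)$b22, -7.77e-2, tolerance = 1e-9)
})
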