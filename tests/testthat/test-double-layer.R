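# Net-charge profiles, exponential decay fits, Poisson-Boltzmann length.

step_profile <- function(r_at, n_bins = 100, bin_width = 0.05) {
  # unnormalised profile with unit counts at given distances
  v <- numeric(n_bins)
  for (d in r_at) {
    b <- min(floor(d / bin_width) + 1L, n_bins)
    v[b] <- v[b] + 1 / bin_width
  }
  structure(list(r = (seq_len(n_bins) - 0.5) * bin_width, value = v,
                 bin_width = bin_width, n_frames = 1, species = "ion"),
            class = "radial_profile")
}

test_that("Qnet is the hand-computed step function on a placed-ion fixture", {
  cat_p <- step_profile(c(0.4, 1.1, 1.8))            # 3 cations
  ani_p <- step_profile(c(0.2, 0.5, 0.9, 1.3, 2.1))  # 5 anions
  qp <- net_charge_profile(cat_p, ani_p, q_protein = 2)
  # below the first ion Qnet = protein charge
  expect_equal(qp$qnet[qp$r < 0.2], rep(2, sum(qp$r < 0.2)))
  hand <- function(r) 2 + sum(c(0.4, 1.1, 1.8) <= r) - sum(c(0.2, 0.5, 0.9, 1.3, 2.1) <= r)
  for (r in c(0.25, 0.45, 0.75, 1.25, 1.95, 2.5, 4.9)) {
    i <- which.min(abs(qp$r - r))
    expect_equal(qp$qnet[i], hand(qp$r[i]))
  }
  # total drop equals -q_protein + (n+ - n-) = exact integer identity
  expect_equal(qp$qnet[length(qp$qnet)], 0)
  expect_error(net_charge_profile(cat_p, step_profile(0.2, n_bins = 50), 2),
               "share grid")
})

test_that("debye_fit recovers an exact exponential to high precision", {
  r <- seq(0.05, 3, by = 0.01)
  qp <- list(r = r, qnet = 2.0 * exp(-r / 0.79))
  fit <- debye_fit(qp)
  expect_equal(fit$A0, 2.0, tolerance = 1e-8)
  expect_equal(fit$zeta, 0.79, tolerance = 1e-8)
  expect_lt(fit$rms_residual, 1e-10)
  # log-linear route agrees on strictly positive data
  fit2 <- debye_fit(qp, method = "log-linear")
  expect_equal(fit2$zeta, 0.79, tolerance = 1e-8)
  # scale equivariance: c * Qnet -> c * A0, same zeta
  qp2 <- list(r = r, qnet = 7 * qp$qnet)
  fit3 <- debye_fit(qp2)
  expect_equal(fit3$A0, 7 * fit$A0, tolerance = 1e-6)
  expect_equal(fit3$zeta, fit$zeta, tolerance = 1e-8)
})

test_that("debye_fit refuses hopeless windows and handles sign dips", {
  r <- seq(0.05, 3, by = 0.02)
  expect_error(debye_fit(list(r = r, qnet = -exp(-r))), "non-positive")
  expect_error(debye_fit(list(r = r[1:5], qnet = exp(-r[1:5]))), "at least 6")
  # a zero-crossing profile still fits in nls mode
  q <- 2 * exp(-r / 0.5) - 0.08
  fit <- debye_fit(list(r = r, qnet = q))
  expect_true(fit$zeta > 0)
  # widening the window past the zero crossing breaks log-linear mode
  expect_error(debye_fit(list(r = r, qnet = q), window = c(0.25, 2.5),
                         method = "log-linear"),
               "non-positive")
})

test_that("white noise leaves the zeta estimate unbiased (Monte Carlo)", {
  r <- seq(0.26, 1.0, by = 0.02)
  a0 <- 11; zeta <- 0.72
  set.seed(121)
  est <- replicate(200, {
    q <- a0 * exp(-r / zeta) + rnorm(length(r), 0, 0.01 * a0)
    debye_fit(list(r = r, qnet = q))$zeta
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - zeta), 3 * se)
})

test_that("PB Debye length reproduces the closed form and its scalings", {
  expect_equal(round(pb_debye_length(78, 0.15, 300), 2), 0.79)
  # quadrupling the concentration halves zeta
  expect_equal(pb_debye_length(78, 0.6, 300),
               pb_debye_length(78, 0.15, 300) / 2, tolerance = 1e-12)
  # independent hand evaluation at eps_r = 51
  k <- list(e = 1.602176634e-19, kB = 1.380649e-23, NA. = 6.02214076e23,
            eps0 = 8.8541878128e-12)
  hand <- sqrt(51 * k$eps0 * k$kB * 300 / (2 * k$e^2 * k$NA. * 0.15e3)) * 1e9
  expect_equal(pb_debye_length(51, 0.15, 300), hand, tolerance = 1e-6)
  # monotone in eps_r and T, decreasing in C
  eps_grid <- c(20, 51, 65, 78, 95, 107)
  expect_true(all(diff(vapply(eps_grid, pb_debye_length, numeric(1),
                              conc = 0.15)) > 0))
  t_grid <- c(280, 300, 320, 350)
  expect_true(all(diff(vapply(t_grid, function(tt)
    pb_debye_length(78, 0.15, tt), numeric(1))) > 0))
  c_grid <- c(0.05, 0.1, 0.15, 0.3, 0.6)
  expect_true(all(diff(vapply(c_grid, function(cc)
    pb_debye_length(78, cc), numeric(1))) < 0))
  expect_error(pb_debye_length(78, -1), "> 0")
})

test_that("synthetic ion cloud recovers its target screening length", {
  spec <- ion_cloud_spec(protein_charge = 11, target_zeta = 0.72,
                         box_edge = 12, n_ion_pairs = 148, seed = 31)
  cl <- gen_ion_cloud(spec, n_frames = 400)
  pid <- select_atoms(cl, species == "protein")
  rc <- surface_rdf(cl, pid, select_atoms(cl, species == "cation"),
                    bin_width = 0.02)
  ra <- surface_rdf(cl, pid, select_atoms(cl, species == "anion"),
                    bin_width = 0.02)
  qp <- net_charge_profile(rc, ra, 11)
  fit <- debye_fit(qp)
  expect_lt(abs(fit$zeta - 0.72) / 0.72, 0.05)
  # exact integer charge conservation at the half-box
  expect_equal(qp$qnet[length(qp$qnet)], 0, tolerance = 1e-9)
})
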