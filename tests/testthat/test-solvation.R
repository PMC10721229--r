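# Surface-minimum-distance RDFs, rescaling, coordination numbers.

two_atom_traj <- function(d = 0.30, box = 10) {
  top <- topology(mass = c(100, 18), species = c("protein", "water"))
  trajectory(top, list(list(coords = rbind(c(5, 5, 5), c(5 + d, 5, 5)),
                            box = rep(box, 3), time = 0)))
}

test_that("a single neighbour lands in one bin with value 1 / bin width", {
  tr <- two_atom_traj(0.302)
  pr <- surface_rdf(tr, 1L, 2L, bin_width = 0.01)
  hit <- which(pr$value > 0)
  expect_length(hit, 1L)
  expect_equal(pr$r[hit], 0.305, tolerance = 1e-9)  # bin [0.30, 0.31)
  expect_equal(pr$value[hit], 100)
  expect_equal(coordination_number(pr, 0.5), 1.0, tolerance = 1e-12)
})

test_that("uniform ideal gas around a point gives a 4 pi r^2 profile", {
  set.seed(71)
  n <- 4000; nf <- 8; box <- 8
  frames <- lapply(seq_len(nf), function(f) {
    list(coords = rbind(rep(box / 2, 3),
                        matrix(runif(n * 3, 0, box), n, 3)),
         box = rep(box, 3), time = f - 1)
  })
  top <- topology(mass = c(100, rep(18, n)),
                  species = c("protein", rep("water", n)))
  tr <- trajectory(top, frames)
  pr <- surface_rdf(tr, 1L, 2:(n + 1L), bin_width = 0.1, r_max = 3)
  rho <- n / box^3
  expected <- 4 * pi * pr$r^2 * rho
  w <- pr$r > 0.5   # skip low-count small-r bins
  expect_lt(mean(abs(pr$value[w] / expected[w] - 1)), 0.05)
})

test_that("profile integral equals the direct mean count (defining identity)", {
  set.seed(81)
  np <- 12; ns <- 120; nf <- 4; box <- 6
  top <- topology(mass = c(rep(100, np), rep(18, ns)),
                  species = c(rep("protein", np), rep("water", ns)))
  frames <- lapply(seq_len(nf), function(f) {
    list(coords = rbind(matrix(runif(np * 3, 2.5, 3.5), np, 3),
                        matrix(runif(ns * 3, 0, box), ns, 3)),
         box = rep(box, 3), time = f - 1)
  })
  tr <- trajectory(top, frames)
  pr <- surface_rdf(tr, 1:np, (np + 1):(np + ns), bin_width = 0.02)
  for (rc in c(0.5, 1.0, 2.0)) {
    direct <- mean(vapply(frames, function(fr) {
      d <- mabsolkit:::min_surface_distances(fr$coords, 1:np,
                                             (np + 1):(np + ns), fr$box)
      sum(d < rc)
    }, numeric(1)))
    expect_equal(coordination_number(pr, rc), direct, tolerance = 1e-9)
  }
  # integral to the last bin equals every species atom in the half-box shell
  total <- coordination_number(pr, max(pr$r) + pr$bin_width / 2)
  direct_all <- mean(vapply(frames, function(fr) {
    d <- mabsolkit:::min_surface_distances(fr$coords, 1:np,
                                           (np + 1):(np + ns), fr$box)
    sum(d < max(pr$r) + pr$bin_width / 2)
  }, numeric(1)))
  expect_equal(total, direct_all, tolerance = 1e-9)
  expect_error(coordination_number(pr, 10), "beyond the last bin")
})

test_that("profiles are invariant under global translation and atom reordering", {
  set.seed(91)
  np <- 5; ns <- 40; box <- 6
  co <- rbind(matrix(runif(np * 3, 2, 4), np, 3),
              matrix(runif(ns * 3, 0, box), ns, 3))
  top <- topology(mass = rep(1, np + ns),
                  species = c(rep("protein", np), rep("water", ns)))
  tr <- trajectory(top, list(list(coords = co, box = rep(box, 3), time = 0)))
  pr <- surface_rdf(tr, 1:np, (np + 1):(np + ns), bin_width = 0.05)
  # translation (with wrap-around handled by minimum image)
  co2 <- sweep(co, 2, c(1.3, -2.1, 0.7), "+")
  tr2 <- trajectory(top, list(list(coords = co2, box = rep(box, 3), time = 0)))
  pr2 <- surface_rdf(tr2, 1:np, (np + 1):(np + ns), bin_width = 0.05)
  expect_equal(pr$value, pr2$value, tolerance = 1e-12)
  # reorder species atoms
  perm <- sample((np + 1):(np + ns))
  co3 <- co; co3[(np + 1):(np + ns), ] <- co[perm, ]
  tr3 <- trajectory(top, list(list(coords = co3, box = rep(box, 3), time = 0)))
  pr3 <- surface_rdf(tr3, 1:np, (np + 1):(np + ns), bin_width = 0.05)
  expect_equal(pr$value, pr3$value, tolerance = 1e-12)
})

test_that("rescaling by the bulk linear fit flattens linear profiles", {
  # exactly linear profile -> rescaled identically 1
  r <- seq(0.005, 2.5, by = 0.01)
  prof <- structure(list(r = r, value = 3 + 2 * r, bin_width = 0.01,
                         n_frames = 1, species = "water"),
                    class = "radial_profile")
  rs <- rescale_rdf(prof)
  expect_equal(rs$value, rep(1, length(r)), tolerance = 1e-12)
  expect_equal(rs$slope, 2, tolerance = 1e-9)
  expect_equal(rs$intercept, 3, tolerance = 1e-9)
  # constant profile -> 1 everywhere
  prof2 <- prof; prof2$value <- rep(5, length(r))
  expect_equal(rescale_rdf(prof2)$value, rep(1, length(r)), tolerance = 1e-12)
  # Gaussian peak on linear background: peak position preserved, bulk -> 1
  peak <- 40 * exp(-(r - 0.3)^2 / (2 * 0.03^2))
  prof3 <- prof; prof3$value <- (3 + 2 * r) + peak
  rs3 <- rescale_rdf(prof3)
  expect_equal(rs3$r[which.max(rs3$value)], r[which.max(peak)],
               tolerance = 0.011)
  w <- r >= 1 & r <= 2
  expect_lt(max(abs(rs3$value[w] - 1)), 1e-6)
  # a fitted line crossing zero inside the support is refused
  prof4 <- prof; prof4$value <- pmax(5 - 4 * r, 0.05)
  expect_error(rescale_rdf(prof4), "crosses zero")
})
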