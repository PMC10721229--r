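# Shared fixture builders and independent mini-oracles. Everything is
# generated in code; no stored data.

# uniform random rotation matrix (independent of the package's internal one)
rand_rot <- function() {
  repeat {
    m <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(m)
    r <- qr.Q(qr_)
    if (det(r) < 0) r[, 1] <- -r[, 1]
    if (abs(det(r) - 1) < 1e-9) return(r)
  }
}

# independent Rg oracle via the pairwise-distance identity
# Rg^2 = sum_ij m_i m_j |r_i - r_j|^2 / (2 M^2)
rg_pairwise <- function(coords, mass) {
  mt <- sum(mass)
  acc <- 0
  n <- nrow(coords)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + mass[i] * mass[j] * sum((coords[i, ] - coords[j, ])^2)
    }
  }
  sqrt(acc / (2 * mt^2))
}

# single-frame trajectory from a coordinate matrix
make_traj <- function(coords, mass = NULL, box = rep(100, 3),
                      species = "protein", charge = 0, element = NA,
                      times = NULL) {
  if (!is.list(coords)) coords <- list(coords)
  if (is.null(mass)) mass <- rep(1, nrow(coords[[1]]))
  top <- topology(mass = mass, species = species, charge = charge,
                  element = element)
  frames <- lapply(seq_along(coords), function(i) {
    list(coords = coords[[i]], box = box,
         time = if (is.null(times)) i - 1 else times[i])
  })
  trajectory(top, frames)
}

# exposed area of sphere 1 (radius r1) partially buried by sphere 2
# (radius r2) at centre distance d: spherical-cap closed form
two_sphere_exposed <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}
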