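# helper: wrap a static configuration as a one-frame (or n-frame) trajectory
static_traj <- function(sys, n_frames = 1L, dielectric = 1) {
  structure(list(frames = rep(list(sys$pos), n_frames),
                 species = sys$species, charge = sys$charge, mass = sys$mass,
                 mol_id = sys$mol_id, wall_pos = sys$wall_pos,
                 wall_charge = sys$wall_charge, geometry = sys$geometry,
                 sigma_s = sys$sigma_s,
                 temperature = rep(NA_real_, n_frames),
                 potential = rep(NA_real_, n_frames),
                 total_energy = rep(NA_real_, n_frames),
                 mode = "static", dielectric = dielectric, seed = 0L,
                 spec = NULL, acceptance = NA_real_),
            class = "edl_trajectory")
}

test_that("an ideal gas gives a flat profile and the density closure holds", {
  ig <- build_fixture("ideal_gas", n = 5000, seed = 3)
  traj <- static_traj(ig)
  prof <- radial_density(traj, "X", bin_width = 2)
  # closure: sum(C * V) * (per-A^3 to mol/L factor inverted) = count
  expect_equal(sum(prof$conc * prof$shell_volume) / 1660.5390671738466, 5000,
               tolerance = 1e-9)
  # flat within 3 sigma per bin under binomial statistics
  p <- prof$shell_volume / sum(prof$shell_volume)
  z <- (prof$mean_count - 5000 * p) / sqrt(5000 * p * (1 - p))
  expect_true(all(abs(z) < 3))
})

test_that("profiles of absent species are zero, and empty trajectories error", {
  ig <- build_fixture("ideal_gas", n = 10, seed = 1)
  traj <- static_traj(ig)
  prof <- radial_density(traj, "Na+", bin_width = 5)
  expect_true(all(prof$conc == 0))
  traj$frames <- list()
  expect_error(radial_density(traj, "X", 1), "empty trajectory")
  expect_error(radial_density(static_traj(ig), "X", 0), "bin_width")
})

test_that("screening factor vanishes for identical profiles and closes to 1 for electroneutral systems", {
  out <- cached_mc_run(1.3, 1)
  na <- radial_density(out$traj, "Na+", 0.5)
  cl <- radial_density(out$traj, "Cl-", 0.5)
  s0 <- screening_factor(na, na, out$system$sigma_s)
  expect_true(all(abs(s0$S_f) < 1e-12))

  scr <- screening_factor(na, cl, out$system$sigma_s)
  expect_equal(scr$S_f[1], 1, tolerance = 1e-3)
  expect_identical(scr$S_f[length(scr$S_f)], 0)
  expect_equal(scr$sigma_s_C_m2, out$system$sigma_s * 16.0217663)

  cl2 <- radial_density(out$traj, "Cl-", 1)
  expect_error(screening_factor(na, cl2, out$system$sigma_s), "mismatched")
  expect_error(screening_factor(na, cl, 0), "sigma_s")
})

test_that("step-function toy profiles integrate to the closed-form shell value", {
  # counterions only, uniform concentration C in the shell [r1, r2]
  geom <- pore_geometry(R_n = 30, L_z = 60)
  edges <- seq(0, 30, by = 0.5)
  mk <- function(conc_vec) {
    structure(list(r_mid = (edges[-1] + edges[-61]) / 2, r_edges = edges,
                   conc = conc_vec, stderr = rep(0, 60),
                   mean_count = rep(0, 60), shell_volume = rep(1, 60),
                   species = "Na+", n_frames = 1, geometry = geom),
              class = "radial_profile")
  }
  C <- 2.0; r1 <- 25; r2 <- 28
  conc <- ifelse(edges[-61] >= r1 & edges[-1] <= r2, C, 0)
  na <- mk(conc); cl <- mk(rep(0, 60))
  sigma_s <- 1e-3
  scr <- screening_factor(na, cl, sigma_s)
  # closed-form: integral of (C/conv) * r/R_n dr over [r1,r2] = C (r2^2-r1^2)/(2 R_n conv)
  conv <- 1e27 / 6.02214076e23
  want <- C / conv * (r2^2 - r1^2) / (2 * 30) / sigma_s
  expect_equal(scr$S_f[1], want, tolerance = 1e-12)
  # inside the shell the cumulative value decreases with r; beyond it, zero
  expect_identical(scr$S_f[scr$r >= r2], rep(0, sum(scr$r >= r2)))
  expect_equal(scr$S_f[scr$r <= r1], rep(want, sum(scr$r <= r1)))

  # planar switch drops the Jacobian
  scr_p <- screening_factor(na, cl, sigma_s, planar = TRUE)
  expect_equal(scr_p$S_f[1], C / conv * (r2 - r1) / sigma_s, tolerance = 1e-12)
})

test_that("radial potential is zero without charges, anchored at the axis, and matches hand superposition", {
  ig <- build_fixture("ideal_gas", n = 20, seed = 2)
  traj0 <- static_traj(ig)
  pot0 <- radial_potential(traj0, bin_width = 5, n_azimuth = 4, n_axial = 2)
  expect_true(all(pot0$phi == 0))

  # a single -1 e wall charge: compare against direct two-term Coulomb
  # arithmetic at explicit probe radii
  sys <- build_fixture("single_ion")
  sys$pos <- matrix(c(5, 0, 30), 1, 3)      # one Na+ at r = 5
  sys$wall_pos <- matrix(c(30, 0, 0), 1, 3)
  sys$wall_charge <- -1
  traj <- static_traj(sys)
  radii <- c(0, 10, 20)
  pot <- radial_potential(traj, n_azimuth = 8, n_axial = 4, radii = radii)
  expect_identical(pot$phi[1], 0)  # phi(r0) = 0 exactly by construction

  # independent evaluation
  Lz <- 60; kV <- 1389.35458 / 96.48533212
  charges <- rbind(c(5, 0, 30, 1), c(30, 0, 0, -1))
  phi_at <- function(p) {
    s <- 0
    for (i in 1:2) {
      d <- p - charges[i, 1:3]
      d[3] <- d[3] - Lz * round(d[3] / Lz)
      s <- s + charges[i, 4] / sqrt(sum(d^2))
    }
    s
  }
  want <- sapply(radii, function(rr) {
    th <- 2 * pi * (0:7) / 8; zs <- Lz * ((1:4) - 0.5) / 4
    probes <- mean(sapply(zs, function(z) sapply(th, function(t)
      phi_at(c(rr * cos(t), rr * sin(t), z)))))
    refs <- mean(sapply(zs, function(z) phi_at(c(0, 0, z))))
    kV * (probes - refs)
  })
  expect_equal(pot$phi, want, tolerance = 1e-10)
})

test_that("probe samples too close to a charge are excluded and counted", {
  sys <- build_fixture("single_ion")
  sys$pos <- matrix(c(10, 0, 30), 1, 3)  # charge right on a probe ring
  traj <- static_traj(sys)
  pot <- radial_potential(traj, n_azimuth = 4, n_axial = 1, radii = c(0, 10))
  expect_gt(pot$n_excluded, 0)
  expect_true(all(is.finite(pot$phi)))
})

test_that("peak location reports wall distance, first inward valley, and degenerate cases", {
  geom <- pore_geometry(R_n = 30, L_z = 60)
  edges <- seq(0, 30, by = 0.5)
  mids <- (edges[-1] + edges[-61]) / 2
  mk <- function(conc) structure(
    list(r_mid = mids, r_edges = edges, conc = conc,
         stderr = rep(0, 60), mean_count = conc, shell_volume = rep(1, 60),
         species = "Na+", n_frames = 1, geometry = geom),
    class = "radial_profile")

  # single-bin spike
  spike <- rep(0, 60); spike[55] <- 3
  pk <- locate_peaks(mk(spike))
  expect_equal(pk$wall_distance, 30 - mids[55])

  # monotone profile: boundary peak, no interior valley
  mono <- locate_peaks(mk(seq(0, 1, length.out = 60)))
  expect_equal(mono$peak_r, mids[60])
  expect_true(is.na(mono$valley_r))

  # two Gaussians with known centres recovered within one bin width
  c1 <- 27.25; c2 <- 22.75
  prof <- 3 * exp(-(mids - c1)^2 / 0.5) + 1.5 * exp(-(mids - c2)^2 / 0.8)
  pk2 <- locate_peaks(mk(prof))
  expect_lt(abs(pk2$peak_r - c1), 0.5)
  # the valley sits between the two modes
  expect_true(pk2$valley_r > c2 && pk2$valley_r < c1)

  # all-zero profile flags no peak rather than erroring
  none <- locate_peaks(mk(rep(0, 60)))
  expect_true(none$no_peak)
  expect_error(locate_peaks(list(conc = c(1, 2), r_mid = c(1, 2),
                                 geometry = geom)), "3 bins")
})
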