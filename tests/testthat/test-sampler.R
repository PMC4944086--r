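test_that("velocity Verlet streams freely without forces and matches the harmonic oscillator", {
  # free streaming
  st <- list(pos = matrix(c(1, 2, 3), 1, 3), vel = matrix(c(0.1, -0.2, 0.3), 1, 3),
             forces = matrix(0, 1, 3), mass = 1)
  out <- velocity_verlet_step(st, function(p) matrix(0, 1, 3), dt = 2,
                              force_to_acc = 1)
  expect_equal(out$pos, st$pos + 2 * st$vel)

  # 1-D harmonic oscillator, omega = 1, dt = 0.01 * period
  dt <- 0.01 * 2 * pi
  st <- list(pos = matrix(c(1, 0, 0), 1, 3), vel = matrix(0, 1, 3),
             forces = matrix(c(-1, 0, 0), 1, 3), mass = 1)
  ffn <- function(p) -p
  n <- 1e4
  E <- numeric(n); x <- numeric(n)
  for (i in seq_len(n)) {
    st <- velocity_verlet_step(st, ffn, dt, force_to_acc = 1)
    E[i] <- 0.5 * sum(st$vel^2) + 0.5 * sum(st$pos^2)
    x[i] <- st$pos[1, 1]
  }
  # symplectic: the energy error oscillates but has no secular drift over
  # 100 periods (compare the first and last period means)
  E0 <- 0.5
  expect_lt(abs(mean(E[(n - 99):n]) - mean(E[1:100])) / E0, 1e-4)
  # and the bounded oscillation stays at the (omega dt)^2 scale
  expect_lt(max(abs(E - E0)) / E0, 1e-3)
  # trajectory matches the analytic cosine over the first period
  tgrid <- dt * seq_len(100)
  expect_lt(max(abs(x[1:100] - cos(tgrid))), 1e-3)
})

test_that("the integrator is time reversible to round-off", {
  g <- pore_geometry(R_n = 12, L_z = 24)
  sys <- build_system(build_spec(concentration = 2.0, n_water = 0,
                                 n_wall_charges = 4, seed = 2, geometry = g))
  ffn <- local({
    cfg <- sys
    function(p) { cfg$pos <- p; total_energy_forces(cfg, rcut = Inf)$forces }
  })
  st0 <- list(pos = sys$pos, vel = sys$vel, forces = ffn(sys$pos),
              mass = sys$mass)
  st1 <- velocity_verlet_step(st0, ffn, dt = 2)
  st1$vel <- -st1$vel
  st2 <- velocity_verlet_step(st1, ffn, dt = 2)
  expect_lt(max(abs(st2$pos - st0$pos)), 1e-10)
  expect_lt(max(abs(st2$vel + st0$vel)), 1e-10)
})

test_that("Berendsen scaling is unity at the target, continuous in dt, and matches direct arithmetic", {
  expect_equal(berendsen_lambda(298, 298, 2, 0.1), 1)
  expect_equal(berendsen_lambda(200, 298, 1e-9, 0.1), 1, tolerance = 1e-9)
  # direct arithmetic oracle at T_inst = 2 T0, dt/tau = 0.02
  expect_equal(berendsen_lambda(596, 298, 2, 0.1),
               sqrt(1 + 0.02 * (0.5 - 1)))
  expect_error(berendsen_lambda(0, 298, 2, 0.1), "undefined scaling")
})

test_that("water constraints restore rigid geometry and conserve momentum", {
  wm <- water_model()
  g <- pore_geometry(R_n = 12, L_z = 24)
  sys <- build_system(build_spec(concentration = 0, n_water = 8,
                                 n_wall_charges = 0, seed = 4, geometry = g))
  # already rigid: unchanged to round-off
  out0 <- constrain_water(sys$pos, sys$mol_id, sys$mass)
  expect_lt(max(abs(out0$pos - sys$pos)), 1e-9)

  # perturb by up to 5% of the bond length and restore
  set.seed(9)
  pert <- sys$pos + matrix(runif(length(sys$pos), -0.05, 0.05), ncol = 3)
  vel <- matrix(rnorm(length(sys$pos), sd = 0.01), ncol = 3)
  p_before <- colSums(vel * sys$mass)
  out <- constrain_water(pert, sys$mol_id, sys$mass, vel = vel)
  for (w in unique(sys$mol_id)) {
    s <- which(sys$mol_id == w)
    d_oh1 <- sqrt(sum((out$pos[s[1], ] - out$pos[s[2], ])^2))
    d_oh2 <- sqrt(sum((out$pos[s[1], ] - out$pos[s[3], ])^2))
    d_hh <- sqrt(sum((out$pos[s[2], ] - out$pos[s[3], ])^2))
    expect_lt(abs(d_oh1 - wm$r_OH), 1e-6)
    expect_lt(abs(d_oh2 - wm$r_OH), 1e-6)
    expect_lt(abs(d_hh - wm$r_HH), 1e-6)
  }
  expect_lt(max(abs(colSums(out$vel * sys$mass) - p_before)), 1e-10)

  # degenerate collinear geometry fails loudly
  bad <- sys$pos
  s <- which(sys$mol_id == 1)
  bad[s[2], ] <- bad[s[1], ] + c(1, 0, 0)
  bad[s[3], ] <- bad[s[1], ] + c(2, 0, 0)
  expect_error(constrain_water(bad, sys$mol_id, sys$mass),
               "constraint failure")
})

test_that("thermostatted explicit dynamics hold the target temperature", {
  cfg <- cached_md_equilibrated()
  th <- run(cfg, run_spec(mode = "md_explicit", n_equil_steps = 300,
                          n_prod_steps = 1200, sample_interval = 5,
                          tau_T = 0.1, rcut = Inf, seed = 5))
  expect_lt(abs(mean(th$temperature) - 298) / 298, 0.02)
})

test_that("NVE dynamics conserve total energy", {
  cfg <- cached_md_equilibrated()
  nve <- run(cfg, run_spec(mode = "md_explicit", n_equil_steps = 0,
                           n_prod_steps = 2000, sample_interval = 10,
                           tau_T = Inf, rcut = Inf, seed = 6))
  E <- nve$total_energy
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-3)
})

test_that("runs are bitwise deterministic given the seed, in both modes", {
  g <- pore_geometry(R_n = 12, L_z = 24)
  sys <- build_system(build_spec(concentration = 2.0, n_water = 0,
                                 n_wall_charges = 4, seed = 2, geometry = g))
  rs <- run_spec(mode = "mc_primitive", n_equil_steps = 20,
                 n_prod_steps = 100, sample_interval = 5, seed = 42)
  t1 <- run(sys, rs); t2 <- run(sys, rs)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$potential, t2$potential)

  cfg <- cached_md_equilibrated()
  rs2 <- run_spec(mode = "md_explicit", n_equil_steps = 0, n_prod_steps = 50,
                  sample_interval = 5, rcut = Inf, seed = 7)
  m1 <- run(cfg, rs2); m2 <- run(cfg, rs2)
  expect_identical(m1$frames, m2$frames)
})

test_that("zero production steps give an empty trajectory with valid metadata", {
  sys <- build_fixture("single_ion")
  tr <- run(sys, run_spec(mode = "mc_primitive", n_prod_steps = 0, seed = 1))
  expect_equal(length(tr$frames), 0)
  expect_equal(tr$mode, "mc_primitive")
  expect_equal(tr$seed, 1L)
})

test_that("Metropolis sampling reproduces Boltzmann shell-occupation ratios (detailed balance)", {
  # two 'states': inner shell r < 20 vs outer shell 20 <= r < R_n of the
  # Steele potential; analytic ratio from quadrature of r exp(-beta u)
  sys <- build_fixture("single_ion")
  traj <- run(sys, run_spec(mode = "mc_primitive", n_equil_steps = 1000,
                            n_prod_steps = 6e4, sample_interval = 30,
                            mc_step = 5, seed = 21))
  r <- vapply(traj$frames, function(p) sqrt(p[1, 1]^2 + p[1, 2]^2), 0)
  n_out <- sum(r >= 20); n_tot <- length(r)

  ffp <- default_species()[["Na+"]]; w <- wall_model()
  beta <- 1 / (0.0083144621 * 298)
  dens <- function(rr) rr * exp(-beta * steele_energy(rr, ffp, w))
  p_out <- integrate(dens, 20, 30 - 1e-9)$value /
    integrate(dens, 0, 30 - 1e-9)$value
  # 3 sigma under binomial counting
  expect_lt(abs(n_out - n_tot * p_out), 3 * sqrt(n_tot * p_out * (1 - p_out)))
})

test_that("integration blowups abort with the offending particle index", {
  sys <- build_fixture("single_ion")
  sys$pos <- matrix(c(25, 0, 10), 1, 3)
  sys$vel <- matrix(c(10, 0, 0), 1, 3)   # 10 A/fs toward the wall
  expect_error(run(sys, run_spec(mode = "md_explicit", n_prod_steps = 10,
                                 seed = 1)),
               "blowup|outside the wall|domain error")
})
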