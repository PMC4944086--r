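test_that("ion counts follow the molarity ratio and restore electroneutrality", {
  expect_equal(ion_counts(0, 1045, 0), c(n_Na = 0L, n_Cl = 0L))
  expect_equal(ion_counts(0, 1045, 8), c(n_Na = 8L, n_Cl = 0L))
  # molarity-ratio oracle evaluated by hand: 0.6 * 1045 / 55.345 = 11.33 -> 11
  n <- as.integer(round(0.6 * 1045 / 55.345))
  expect_equal(ion_counts(0.6, 1045, 0), c(n_Na = n, n_Cl = n))
  expect_error(ion_counts(-1, 10, 0), ">= 0")
})

test_that("wall charges sit exactly on the cylinder, equally spaced in z, with the recorded surface density", {
  g <- pore_geometry(R_n = 30, L_z = 60)
  w0 <- place_wall_charges(g, 0)
  expect_equal(nrow(w0), 0)
  expect_equal(attr(w0, "sigma_s"), 0)

  w8 <- place_wall_charges(g, 8, seed = 4)
  r <- sqrt(w8[, 1]^2 + w8[, 2]^2)
  expect_equal(r, rep(30, 8), tolerance = 1e-12)
  expect_equal(diff(w8[, 3]), rep(7.5, 7))
  # area-formula oracle
  expect_equal(attr(w8, "sigma_s"), 8 / (2 * pi * 30 * 60))
  expect_equal(attr(w8, "sigma_s_C_m2"), 8 / (2 * pi * 30 * 60) * 16.0217663)
})

test_that("built systems are electroneutral, inside the pore, and respect the separation rule", {
  spec <- build_spec(concentration = 1.3, n_water = 40, n_wall_charges = 6,
                     seed = 11, geometry = pore_geometry(R_n = 15, L_z = 30))
  sys <- build_system(spec)
  expect_equal(total_charge(sys), 0)
  r <- sqrt(sys$pos[, 1]^2 + sys$pos[, 2]^2)
  expect_true(all(r < 15))
  counts <- ion_counts(1.3, 40, 6)
  expect_equal(sum(sys$species == "Na+"), unname(counts["n_Na"]))
  expect_equal(sum(sys$species == "Cl-"), unname(counts["n_Cl"]))
  expect_equal(sum(sys$species == "O"), 40)
  expect_equal(sum(sys$species == "H"), 80)

  # separation invariant on LJ sites (ions + O)
  ff <- forcefield()
  lj <- sys$species %in% c("Na+", "Cl-", "O")
  p <- sys$pos[lj, ]; spn <- sys$species[lj]
  for (i in seq_len(nrow(p) - 1)) {
    d <- sweep(p[(i + 1):nrow(p), , drop = FALSE], 2, p[i, ])
    d[, 3] <- d[, 3] - 30 * round(d[, 3] / 30)
    dist <- sqrt(rowSums(d^2))
    min_sep <- 0.8 * ff$sigma[spn[(i + 1):nrow(p)], spn[i]]
    expect_true(all(dist >= min_sep - 1e-9))
  }

  # velocities: centre-of-mass momentum removed
  expect_lt(max(abs(colSums(sys$vel * sys$mass))), 1e-10)
})

test_that("the build is a pure function of its spec, and degenerate specs give empty systems", {
  spec <- build_spec(concentration = 2, n_water = 20, n_wall_charges = 4,
                     seed = 5, geometry = pore_geometry(R_n = 12, L_z = 24))
  a <- build_system(spec); b <- build_system(spec)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)

  empty <- build_system(build_spec(concentration = 0, n_water = 0,
                                   n_wall_charges = 0, seed = 1))
  expect_equal(nrow(empty$pos), 0)
  expect_equal(total_charge(empty), 0)
})

test_that("impossible packings fail with an error naming the limiting species", {
  spec <- build_spec(concentration = 0, n_water = 500, n_wall_charges = 0,
                     seed = 1, geometry = pore_geometry(R_n = 5, L_z = 8))
  expect_error(build_system(spec, max_tries = 50L), "packing failure.*O")
})

test_that("fixtures have the advertised composition", {
  si <- build_fixture("single_ion")
  expect_equal(length(si$species), 1L)
  expect_equal(si$species, "Na+")
  expect_equal(length(si$wall_charge), 0L)

  ig <- build_fixture("ideal_gas", n = 4000, seed = 2)
  expect_equal(nrow(ig$pos), 4000)
  r2 <- ig$pos[, 1]^2 + ig$pos[, 2]^2
  # uniform in the cylinder volume: E[r^2] = R^2/2, sd of mean ~ R^2/sqrt(12 n)
  expect_lt(abs(mean(r2) - 30^2 / 2), 4 * 30^2 / sqrt(12 * 4000))

  tc <- build_fixture("two_charge")
  expect_equal(total_charge(tc), 0)
  expect_error(build_fixture("nope"), "arg")
})
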