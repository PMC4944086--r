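# Shared fixtures. Production-style MC runs are memoised per session so
# several tests can reuse the same trajectory without re-sampling.

.run_cache <- new.env(parent = emptyenv())

# implicit-solvent production run at the study conditions (1045 waters'
# worth of salt, 8 wall charges, 3 nm pore)
cached_mc_run <- function(conc, seed, n_equil = 500L, n_prod = 2500L,
                          sample_interval = 5L) {
  key <- sprintf("mc_%g_%d_%d_%d", conc, seed, n_equil, n_prod)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sys <- build_system(build_spec(concentration = conc, seed = seed))
  traj <- run(sys, run_spec(mode = "mc_primitive", n_equil_steps = n_equil,
                            n_prod_steps = n_prod,
                            sample_interval = sample_interval,
                            seed = seed + 100L))
  out <- list(system = sys, traj = traj)
  .run_cache[[key]] <- out
  out
}

# small equilibrated explicit-water system for integrator tests
cached_md_equilibrated <- function() {
  key <- "md_equil"
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  g <- pore_geometry(R_n = 12, L_z = 24)
  sys <- build_system(build_spec(concentration = 2.0, n_water = 16,
                                 n_wall_charges = 4, seed = 2, geometry = g))
  sys <- minimize_config(sys, rcut = Inf, n_steps = 400)
  eq <- run(sys, run_spec(mode = "md_explicit", n_equil_steps = 0,
                          n_prod_steps = 3000, sample_interval = 3000,
                          tau_T = 0.05, rcut = Inf, seed = 3))
  .run_cache[[key]] <- eq$final_config
  eq$final_config
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
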