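#' Generate an equilibrium trajectory
#'
#' `md_explicit` propagates all mobile sites (ions + rigid SPC/E waters) with
#' velocity-Verlet dynamics, SHAKE/RATTLE water constraints and Berendsen
#' thermostatting. `mc_primitive` is the implicit-solvent fast mode: waters
#' are replaced by a dielectric continuum (relative permittivity
#' `spec$dielectric`, default 78.4) and the ions are sampled by Metropolis
#' single-particle displacement moves (detailed balance), feeling the Steele
#' wall, ion-ion LJ cores and screened Coulomb interactions with each other
#' and the frozen wall charges.
#'
#' Runs are pure functions of `(config, spec)` including the seed.
#'
#' @param config An `edl_system` from [build_system()] or [build_fixture()].
#' @param spec A [run_spec()].
#' @param ff A [forcefield()].
#' @param wall A [wall_model()] matching the configuration's pore radius.
#' @return Object of class `edl_trajectory`: `frames` (list of N x 3 position
#'   matrices), per-frame `temperature` (K; `NA` in MC mode), `potential` and
#'   `total_energy` (kJ/mol), the frozen wall sites, geometry, `sigma_s`, and
#'   run metadata (`mode`, `dielectric`, `seed`, `spec`).
#' @export
run <- function(config, spec, ff = forcefield(),
                wall = wall_model(R_n = config$geometry$R_n)) {
  stopifnot(inherits(config, "edl_system"), inherits(spec, "run_spec"))
  if (spec$mode == "mc_primitive") mc_primitive_run(config, spec, ff, wall)
  else md_explicit_run(config, spec, ff, wall)
}

new_trajectory <- function(frames, species, charge, mass, mol_id, config,
                           temperature, potential, total_energy, spec,
                           dielectric, acceptance = NA_real_,
                           final_config = NULL) {
  structure(list(frames = frames, species = species, charge = charge,
                 mass = mass, mol_id = mol_id,
                 wall_pos = config$wall_pos, wall_charge = config$wall_charge,
                 geometry = config$geometry, sigma_s = config$sigma_s,
                 temperature = temperature, potential = potential,
                 total_energy = total_energy,
                 mode = spec$mode, dielectric = dielectric,
                 seed = spec$seed, spec = spec,
                 acceptance = acceptance, final_config = final_config),
            class = "edl_trajectory")
}

#' @export
print.edl_trajectory <- function(x, ...) {
  cat(sprintf("<edl_trajectory> %s: %d frames of %d mobile sites, %d wall charges\n",
              x$mode, length(x$frames), length(x$species), length(x$wall_charge)))
  if (length(x$temperature) && any(is.finite(x$temperature)))
    cat(sprintf("  mean T %.1f K; ", mean(x$temperature, na.rm = TRUE)))
  if (length(x$potential))
    cat(sprintf("mean U %.2f kJ/mol", mean(x$potential)))
  cat(sprintf("\n  seed %d; pore R_n %.1f A, L_z %.1f A\n",
              x$seed, x$geometry$R_n, x$geometry$L_z))
  invisible(x)
}

#' @export
summary.edl_trajectory <- function(object, ...) {
  out <- list(mode = object$mode, n_frames = length(object$frames),
              n_mobile = length(object$species),
              n_wall = length(object$wall_charge),
              mean_temperature = mean(object$temperature, na.rm = TRUE),
              mean_potential = if (length(object$potential)) mean(object$potential) else NA_real_,
              acceptance = object$acceptance,
              sigma_s = object$sigma_s)
  class(out) <- "summary.edl_trajectory"
  out
}

#' @export
print.summary.edl_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d frames, %d mobile sites, %d wall charges\n",
              x$mode, x$n_frames, x$n_mobile, x$n_wall))
  cat(sprintf("  mean T %.2f K, mean U %.3f kJ/mol, sigma_s %.4g e/A^2\n",
              x$mean_temperature, x$mean_potential, x$sigma_s))
  if (is.finite(x$acceptance))
    cat(sprintf("  MC acceptance %.1f%%\n", 100 * x$acceptance))
  invisible(x)
}

## ---- explicit-water molecular dynamics ------------------------------------

md_explicit_run <- function(config, spec, ff, wall) {
  geom <- config$geometry
  n <- nrow(config$pos)
  n_water <- length(unique(config$mol_id[!is.na(config$mol_id)]))
  dof <- 3L * n - 3L * n_water
  wm <- water_model()
  has_water <- n_water > 0L

  cache <- new.env(parent = emptyenv())
  cfg <- config
  force_fn <- function(pos) {
    cfg$pos <- pos
    out <- total_energy_forces(cfg, ff = ff, wall = wall,
                               method = "cutoff_rf", rcut = spec$rcut,
                               dielectric = 1)
    cache$U <- out$energy
    out$forces
  }

  with_seed(spec$seed, {
    state <- list(pos = config$pos, vel = config$vel,
                  forces = force_fn(config$pos), mass = config$mass)
    n_total <- spec$n_equil_steps + spec$n_prod_steps
    n_frames <- if (spec$n_prod_steps > 0L)
      spec$n_prod_steps %/% spec$sample_interval else 0L
    frames <- vector("list", n_frames)
    temperature <- potential <- total_energy <- numeric(n_frames)
    k <- 0L
    for (step in seq_len(n_total)) {
      state <- velocity_verlet_step(state, force_fn, spec$dt,
                                    mol_id = if (has_water) config$mol_id,
                                    water = if (has_water) wm,
                                    R_n = geom$R_n)
      ke <- 0.5 * sum(state$mass * rowSums(state$vel^2)) / .acc_unit
      T_inst <- 2 * ke / (dof * .kB)
      if (is.finite(spec$tau_T)) {
        lam <- berendsen_lambda(T_inst, spec$T0, spec$dt, spec$tau_T)
        state$vel <- state$vel * lam
      }
      if (step > spec$n_equil_steps &&
          (step - spec$n_equil_steps) %% spec$sample_interval == 0L) {
        k <- k + 1L
        frames[[k]] <- state$pos
        temperature[k] <- T_inst
        potential[k] <- cache$U
        total_energy[k] <- cache$U + ke
      }
    }
    fin <- config
    fin$pos <- state$pos; fin$vel <- state$vel
    new_trajectory(frames, config$species, config$charge, config$mass,
                   config$mol_id, config, temperature, potential,
                   total_energy, spec, dielectric = 1, final_config = fin)
  })
}

## ---- implicit-solvent Metropolis Monte Carlo ------------------------------

mc_primitive_run <- function(config, spec, ff, wall) {
  keep <- is.na(config$mol_id)
  sp <- config$species[keep]
  q <- config$charge[keep]
  pos <- config$pos[keep, , drop = FALSE]
  n <- length(sp)
  geom <- config$geometry
  Lz <- geom$L_z; R_n <- geom$R_n
  eps_r <- spec$dielectric
  beta <- 1 / (.kB * spec$T0)

  ## pair tables: Aij = 4 eps sigma^12, Bij = 4 eps sigma^6, Kij = k qi qj / eps_r
  sig <- ff$sigma[sp, sp, drop = FALSE]
  eps <- ff$epsilon[sp, sp, drop = FALSE]
  Amat <- 4 * eps * sig^12
  Bmat <- 4 * eps * sig^6
  Kmat <- .k_coulomb * outer(q, q) / eps_r

  ## wall charges
  wx <- config$wall_pos[, 1L]; wy <- config$wall_pos[, 2L]
  wz <- config$wall_pos[, 3L]
  # per-ion prefactor for the frozen -1 e wall charges, screened like all
  # other Coulomb terms by the continuum dielectric
  kw <- .k_coulomb * q * (if (length(config$wall_charge)) -1 else 0) / eps_r
  m_wall <- length(wz)

  ## Steele constants per ion
  swf <- pref <- numeric(n)
  for (s in unique(sp)) {
    i <- sp == s
    spar <- ff$species[[s]]
    if (spar$epsilon > 0) {
      mx <- wall_mixing(wall, spar)
      swf[i] <- mx$sigma_wf
      pref[i] <- 2 * pi * wall$rho_w_A3 * mx$epsilon_wf * mx$sigma_wf^2 * wall$Delta
    }
  }
  Delta <- wall$Delta

  steele_u <- function(i, rad) {
    if (pref[i] == 0) return(0)
    z <- R_n - rad
    s <- swf[i]
    pref[i] * (0.4 * (s / z)^10 - (s / z)^4 -
               s^4 / (3 * Delta * (z + 0.61 * Delta)^3))
  }

  px <- pos[, 1L]; py <- pos[, 2L]; pz <- pos[, 3L]

  ion_energy <- function(i, x, y, z) {
    rad <- sqrt(x * x + y * y)
    if (rad >= R_n - 1e-9) return(Inf)
    e <- steele_u(i, rad)
    if (n > 1L) {
      dx <- px - x; dy <- py - y; dz <- pz - z
      dz <- dz - Lz * round(dz / Lz)
      r2 <- dx * dx + dy * dy + dz * dz
      r2[i] <- Inf
      r6 <- r2 * r2 * r2
      e <- e + sum(Amat[, i] / (r6 * r6) - Bmat[, i] / r6) +
        sum(Kmat[, i] / sqrt(r2))
    }
    if (m_wall > 0L) {
      dwx <- wx - x; dwy <- wy - y; dwz <- wz - z
      dwz <- dwz - Lz * round(dwz / Lz)
      e <- e + kw[i] * sum(1 / sqrt(dwx * dwx + dwy * dwy + dwz * dwz))
    }
    e
  }

  total_energy <- function() {
    e <- 0
    for (i in seq_len(n)) e <- e + ion_energy(i, px[i], py[i], pz[i])
    # pair terms counted twice, wall/Steele once each; recombine:
    e_wall <- 0
    for (i in seq_len(n)) {
      rad <- sqrt(px[i]^2 + py[i]^2)
      e_wall <- e_wall + steele_u(i, rad)
      if (m_wall > 0L) {
        dwz <- wz - pz[i]; dwz <- dwz - Lz * round(dwz / Lz)
        e_wall <- e_wall + kw[i] * sum(1 / sqrt((wx - px[i])^2 + (wy - py[i])^2 + dwz^2))
      }
    }
    (e - e_wall) / 2 + e_wall
  }

  with_seed(spec$seed, {
    n_sweeps <- spec$n_equil_steps + spec$n_prod_steps
    n_frames <- if (spec$n_prod_steps > 0L)
      spec$n_prod_steps %/% spec$sample_interval else 0L
    frames <- vector("list", n_frames)
    potential <- numeric(n_frames)
    n_acc <- 0L; n_try <- 0L
    k <- 0L
    delta <- spec$mc_step
    for (sweep in seq_len(n_sweeps)) {
      if (n > 0L) {
        idx <- sample.int(n, n, replace = TRUE)
        disp <- matrix(stats::runif(3L * n, -delta, delta), n, 3L)
        uacc <- stats::runif(n)
        for (t in seq_len(n)) {
          i <- idx[t]
          e_old <- ion_energy(i, px[i], py[i], pz[i])
          xn <- px[i] + disp[t, 1L]; yn <- py[i] + disp[t, 2L]
          zn <- pz[i] + disp[t, 3L]
          zn <- zn - Lz * floor(zn / Lz)
          e_new <- ion_energy(i, xn, yn, zn)
          dE <- e_new - e_old
          n_try <- n_try + 1L
          if (dE <= 0 || uacc[t] < exp(-beta * dE)) {
            px[i] <- xn; py[i] <- yn; pz[i] <- zn
            n_acc <- n_acc + 1L
          }
        }
      }
      if (sweep > spec$n_equil_steps &&
          (sweep - spec$n_equil_steps) %% spec$sample_interval == 0L) {
        k <- k + 1L
        fr <- cbind(x = px, y = py, z = pz)
        frames[[k]] <- fr
        potential[k] <- total_energy()
      }
    }
    fin <- config
    fin$species <- sp; fin$charge <- q; fin$mass <- config$mass[keep]
    fin$mol_id <- rep(NA_integer_, n)
    fin$pos <- cbind(x = px, y = py, z = pz)
    fin$vel <- matrix(0, n, 3)
    new_trajectory(frames, sp, q, config$mass[keep],
                   rep(NA_integer_, n), config,
                   temperature = rep(NA_real_, n_frames),
                   potential = potential,
                   total_energy = rep(NA_real_, n_frames),
                   spec = spec, dielectric = eps_r,
                   acceptance = if (n_try > 0L) n_acc / n_try else NA_real_,
                   final_config = fin)
  })
}
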