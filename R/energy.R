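# Total potential energy and forces: LJ pairs + Steele wall + electrostatics.

#' Total potential energy and forces of a configuration
#'
#' Sums Lennard-Jones pair interactions (Lorentz-Berthelot mixed, truncated
#' and shifted at `rcut`), the Steele 10-4-3 wall term for LJ-active species,
#' and point-charge electrostatics (reaction-field cutoff by default, Ewald
#' optionally). Intramolecular water pairs are excluded from LJ and Coulomb.
#' Frozen wall charges contribute energy and exert forces on mobile sites but
#' receive none. Forces are the negative analytic gradients.
#'
#' @param config An `edl_system`.
#' @param ff A [forcefield()].
#' @param wall A [wall_model()]; defaults to the configuration's pore radius.
#' @param method Electrostatics method, `"cutoff_rf"` or `"ewald"`.
#' @param rcut Cutoff (A) for LJ and reaction-field Coulomb; `Inf` disables
#'   truncation (plain 1/r, minimum image along z) — exactly conservative,
#'   used for energy-conservation checks.
#' @param dielectric Relative dielectric constant (1 for explicit solvent).
#' @return List with `energy` (kJ/mol), `forces` (N x 3, kJ/mol/A, mobile
#'   sites only) and `breakdown` (named vector: lj, steele, coulomb).
#' @export
total_energy_forces <- function(config, ff = forcefield(),
                                wall = wall_model(R_n = config$geometry$R_n),
                                method = c("cutoff_rf", "ewald"),
                                rcut = NULL, dielectric = 1) {
  method <- match.arg(method)
  n <- nrow(config$pos)
  geom <- config$geometry
  if (is.null(rcut)) rcut <- min(geom$L_z, 2 * geom$R_n) / 2
  forces <- matrix(0, n, 3)
  if (n == 0L)
    return(list(energy = 0, forces = forces,
                breakdown = c(lj = 0, steele = 0, coulomb = 0)))

  nw <- nrow(config$wall_pos)
  all_pos <- rbind(config$pos, config$wall_pos)
  all_q <- c(config$charge, config$wall_charge)
  all_sp <- c(config$species, rep("WALLQ", nw))
  ntot <- nrow(all_pos)

  e_lj <- 0; e_coul <- 0
  if (ntot > 1L) {
    pv <- .pair_vectors(all_pos, geom$L_z)
    r <- pv$r
    if (any(r < 0.1)) {
      k <- which(r < 0.1)[1L]
      stop(sprintf("overlap error: particles %d and %d at %.3f A",
                   pv$i[k], pv$j[k], r[k]))
    }
    excl <- water_exclusions(config$mol_id)
    keep <- rep(TRUE, length(r))
    if (!is.null(excl) && nrow(excl) > 0L) {
      key <- paste(pv$i, pv$j)
      keep <- !(key %in% paste(excl[, 1L], excl[, 2L]))
    }

    ## LJ (truncated + shifted so u(rcut) = 0)
    eps <- ff$epsilon[cbind(all_sp[pv$i], all_sp[pv$j])]
    sig <- ff$sigma[cbind(all_sp[pv$i], all_sp[pv$j])]
    sel <- keep & eps > 0 & r < rcut
    if (any(sel)) {
      sr6 <- (sig[sel] / r[sel])^6
      u <- 4 * eps[sel] * (sr6^2 - sr6)
      if (is.finite(rcut)) {
        src6 <- (sig[sel] / rcut)^6
        u <- u - 4 * eps[sel] * (src6^2 - src6)
      }
      e_lj <- sum(u)
      fmag <- 4 * eps[sel] * (12 * sr6^2 - 6 * sr6) / r[sel]
      forces <- accumulate_pair_forces(forces, pv, sel, fmag, n)
    }

    ## electrostatics
    qq <- all_q[pv$i] * all_q[pv$j]
    if (method == "cutoff_rf" && is.finite(rcut)) {
      sel <- keep & qq != 0 & r < rcut
      if (any(sel)) {
        e_coul <- sum(.rf_energy(r[sel], qq[sel], rcut, dielectric))
        fmag <- .rf_force(r[sel], qq[sel], rcut, dielectric)
        forces <- accumulate_pair_forces(forces, pv, sel, fmag, n)
      }
    } else if (method == "cutoff_rf") {       # rcut = Inf: plain direct sum
      sel <- keep & qq != 0
      if (any(sel)) {
        e_coul <- sum(.k_coulomb * qq[sel] / (dielectric * r[sel]))
        fmag <- .k_coulomb * qq[sel] / (dielectric * r[sel]^2)
        forces <- accumulate_pair_forces(forces, pv, sel, fmag, n)
      }
    } else {
      box <- c(4 * geom$R_n, 4 * geom$R_n, geom$L_z)
      ew <- ewald_energy(all_pos, all_q, box, forces = TRUE,
                         exclude = water_exclusions(config$mol_id))
      e_coul <- ew$energy / dielectric
      forces <- forces + ew$forces[seq_len(n), , drop = FALSE] / dielectric
    }
  }

  ## Steele wall on LJ-active mobile species
  e_st <- 0
  active <- which(vapply(config$species,
                         function(s) ff$species[[s]]$epsilon > 0, TRUE))
  if (length(active) > 0L) {
    rr <- sqrt(config$pos[active, 1L]^2 + config$pos[active, 2L]^2)
    if (any(rr >= geom$R_n))
      stop("domain error: particle at or outside the wall (r >= R_n)")
    for (s in unique(config$species[active])) {
      idx <- active[config$species[active] == s]
      rs <- rr[match(idx, active)]
      e_st <- e_st + sum(steele_energy(rs, ff$species[[s]], wall))
      fr <- steele_force(rs, ff$species[[s]], wall)
      pos_r <- pmax(rs, 1e-12)
      forces[idx, 1L] <- forces[idx, 1L] + fr * config$pos[idx, 1L] / pos_r
      forces[idx, 2L] <- forces[idx, 2L] + fr * config$pos[idx, 2L] / pos_r
    }
  }

  list(energy = e_lj + e_st + e_coul, forces = forces,
       breakdown = c(lj = e_lj, steele = e_st, coulomb = e_coul))
}

# add central pair forces of magnitude fmag (positive = repulsive) along the
# pair vectors of pv[sel]; only mobile sites (index <= n) receive force
accumulate_pair_forces <- function(forces, pv, sel, fmag, n) {
  d <- pv$d[sel, , drop = FALSE]
  r <- pv$r[sel]
  fv <- d * (fmag / r)            # force on j (d = x_j - x_i)
  i <- pv$i[sel]; j <- pv$j[sel]
  for (k in 1:3) {
    add_j <- tabulate_add(j[j <= n], fv[j <= n, k], n)
    add_i <- tabulate_add(i[i <= n], fv[i <= n, k], n)
    forces[, k] <- forces[, k] + add_j - add_i
  }
  forces
}

#' Kinetic energy and instantaneous temperature
#'
#' Kinetic energy in kJ/mol and the instantaneous temperature counting only
#' unconstrained degrees of freedom (3 per site minus 3 per rigid water).
#'
#' @param config An `edl_system` (uses `vel`, `mass`, `mol_id`).
#' @return List with `kinetic` (kJ/mol), `temperature` (K), `dof`.
#' @export
kinetic_temperature <- function(config) {
  ke <- 0.5 * sum(config$mass * rowSums(config$vel^2)) / .acc_unit
  n_water <- length(unique(config$mol_id[!is.na(config$mol_id)]))
  dof <- 3L * nrow(config$pos) - 3L * n_water
  list(kinetic = ke,
       temperature = if (dof > 0) 2 * ke / (dof * .kB) else NA_real_,
       dof = dof)
}
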