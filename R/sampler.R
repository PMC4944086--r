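#' Run specification for the samplers
#'
#' In `md_explicit` mode the step counts are velocity-Verlet steps of `dt`
#' fs; in `mc_primitive` mode they are Metropolis sweeps (one attempted
#' displacement per mobile ion), waters are replaced by a dielectric
#' continuum, and `dt`/`T0`/`tau_T` keep their thermodynamic meaning where
#' applicable.
#'
#' @param dt Time step in fs (default 2).
#' @param T0 Target temperature in K (default 298.0).
#' @param tau_T Berendsen time constant in ps (default 0.1); `Inf` disables
#'   the thermostat (NVE).
#' @param n_equil_steps Discarded equilibration steps/sweeps.
#' @param n_prod_steps Production steps/sweeps.
#' @param sample_interval Record one frame every this many steps/sweeps.
#' @param mode `"md_explicit"` or `"mc_primitive"`.
#' @param seed RNG seed; identical (config, spec) including seed give
#'   bitwise-identical trajectories.
#' @param dielectric Continuum relative dielectric constant used by
#'   `mc_primitive` (default 78.4; explicit mode uses 1).
#' @param mc_step Maximum Monte-Carlo displacement per axis (A, default 1).
#' @param rcut Interaction cutoff (A) for explicit mode; `NULL` for the
#'   geometric default, `Inf` for untruncated sums.
#' @return Object of class `run_spec`.
#' @export
run_spec <- function(dt = 2, T0 = 298.0, tau_T = 0.1,
                     n_equil_steps = 0L, n_prod_steps = 0L,
                     sample_interval = 1L,
                     mode = c("md_explicit", "mc_primitive"),
                     seed = 1L, dielectric = 78.4, mc_step = 1.0,
                     rcut = NULL) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be > 0")
  if (T0 <= 0) stop("T0 must be > 0")
  if (is.finite(tau_T) && tau_T * 1000 < dt) stop("tau_T must be >= dt")
  structure(list(dt = dt, T0 = T0, tau_T = tau_T,
                 n_equil_steps = as.integer(n_equil_steps),
                 n_prod_steps = as.integer(n_prod_steps),
                 sample_interval = as.integer(sample_interval),
                 mode = mode, seed = as.integer(seed),
                 dielectric = dielectric, mc_step = mc_step, rcut = rcut),
            class = "run_spec")
}

#' Berendsen weak-coupling velocity scale factor
#'
#' \eqn{\lambda = \sqrt{1 + (dt/\tau)(T_0/T_{inst} - 1)}}; all mobile
#' velocities are multiplied by this each step to drive the instantaneous
#' temperature toward `T0` with time constant `tau`.
#'
#' @param T_inst Instantaneous temperature (K), > 0.
#' @param T0 Target temperature (K).
#' @param dt Time step (fs).
#' @param tau Coupling time constant (ps).
#' @return Scale factor lambda.
#' @export
berendsen_lambda <- function(T_inst, T0, dt, tau) {
  if (any(T_inst <= 0)) stop("undefined scaling: T_inst must be > 0")
  sqrt(1 + (dt / (tau * 1000)) * (T0 / T_inst - 1))
}

#' One velocity-Verlet step
#'
#' Standard half-kick / drift / half-kick update. When `mol_id` and `water`
#' are supplied, rigid-water constraints are applied to the drifted positions
#' (SHAKE against the pre-step geometry) and to the final velocities
#' (RATTLE), so constrained bonds stay at their model lengths.
#'
#' @param state List with `pos` (n x 3), `vel` (n x 3), `forces` (n x 3) and
#'   `mass` (length n).
#' @param force_fn Function `pos -> n x 3 forces` consistent with `state$pos`
#'   on entry.
#' @param dt Time step (fs for the default unit conversion).
#' @param mol_id Optional water molecule index per site (`NA` for ions).
#' @param water Optional [water_model()] defining the rigid geometry.
#' @param R_n Optional pore radius: any site reaching `r >= R_n` aborts with
#'   an integration-blowup error naming the site.
#' @param force_to_acc Conversion from force/mass to acceleration in the
#'   position units per `dt` unit squared; the default 1e-4 converts
#'   kJ/mol/A per g/mol to A/fs^2. Pass 1 for self-consistent toy units.
#' @return Updated state (positions, velocities, forces).
#' @export
velocity_verlet_step <- function(state, force_fn, dt, mol_id = NULL,
                                 water = NULL, R_n = NULL,
                                 force_to_acc = .acc_unit) {
  m <- state$mass
  v <- state$vel + 0.5 * dt * force_to_acc * state$forces / m
  pos_old <- state$pos
  pos <- pos_old + dt * v
  if (!is.null(mol_id) && !is.null(water) && any(!is.na(mol_id))) {
    sh <- shake_water(pos, pos_old, mol_id, m, water)
    v <- v + (sh - pos) / dt
    pos <- sh
  }
  if (!is.null(R_n)) {
    rr <- sqrt(pos[, 1L]^2 + pos[, 2L]^2)
    if (any(rr >= R_n))
      stop(sprintf("integration blowup: particle %d reached r = %.2f A >= R_n",
                   which.max(rr), max(rr)))
  }
  f <- force_fn(pos)
  v <- v + 0.5 * dt * force_to_acc * f / m
  if (!is.null(mol_id) && !is.null(water) && any(!is.na(mol_id)))
    v <- rattle_water(pos, v, mol_id, m)
  list(pos = pos, vel = v, forces = f, mass = m)
}

# constraint index triples (O, H1, H2) per water molecule
.water_triples <- function(mol_id) {
  ids <- unique(mol_id[!is.na(mol_id)])
  iO <- iH1 <- iH2 <- integer(length(ids))
  for (k in seq_along(ids)) {
    s <- which(!is.na(mol_id) & mol_id == ids[k])
    if (length(s) != 3L) stop("water molecule ", ids[k], " does not have 3 sites")
    iO[k] <- s[1L]; iH1[k] <- s[2L]; iH2[k] <- s[3L]
  }
  list(iO = iO, iH1 = iH1, iH2 = iH2)
}

# iterative SHAKE: restore O-H, O-H, H-H distances using reference vectors;
# mass-weighted so each molecule's centre of mass (and total momentum when
# used inside the integrator) is preserved
shake_water <- function(pos, ref, mol_id, mass, water = water_model(),
                        tol = 1e-10, max_iter = 500L) {
  tri <- .water_triples(mol_id)
  cons <- list(list(a = tri$iO,  b = tri$iH1, d = water$r_OH),
               list(a = tri$iO,  b = tri$iH2, d = water$r_OH),
               list(a = tri$iH1, b = tri$iH2, d = water$r_HH))
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (cc in cons) {
      a <- cc$a; b <- cc$b; d2 <- cc$d^2
      s <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
      rs <- ref[b, , drop = FALSE] - ref[a, , drop = FALSE]
      diff <- rowSums(s * s) - d2
      worst <- max(worst, max(abs(sqrt(rowSums(s * s)) - cc$d)))
      inv <- 1 / mass[a] + 1 / mass[b]
      g <- diff / (2 * inv * rowSums(s * rs))
      pos[a, ] <- pos[a, ] + (g / mass[a]) * rs
      pos[b, ] <- pos[b, ] - (g / mass[b]) * rs
    }
    if (!is.finite(worst) || any(!is.finite(pos)))
      stop("constraint failure: degenerate (collinear) water geometry")
    if (worst < tol) break
  }
  if (worst >= 1e-6) {
    stop(sprintf("constraint failure: residual %.3g A after %d iterations",
                 worst, max_iter))
  }
  pos
}

# RATTLE: project out relative velocity along each constrained bond
rattle_water <- function(pos, vel, mol_id, mass, tol = 1e-12,
                         max_iter = 200L) {
  tri <- .water_triples(mol_id)
  cons <- list(c(1, 2), c(1, 3), c(2, 3))
  idx <- cbind(tri$iO, tri$iH1, tri$iH2)
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (cc in cons) {
      a <- idx[, cc[1L]]; b <- idx[, cc[2L]]
      s <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
      dv <- vel[b, , drop = FALSE] - vel[a, , drop = FALSE]
      num <- rowSums(s * dv)
      worst <- max(worst, max(abs(num)))
      inv <- 1 / mass[a] + 1 / mass[b]
      k <- num / (rowSums(s * s) * inv)
      vel[a, ] <- vel[a, ] + (k / mass[a]) * s
      vel[b, ] <- vel[b, ] - (k / mass[b]) * s
    }
    if (worst < tol) break
  }
  vel
}

#' Restore rigid SPC/E geometry of water molecules
#'
#' Iterative mass-weighted constraint projection: O-H and H-H distances are
#' driven back to the model values (to well below 1e-6 A) while each
#' molecule's centre of mass is preserved; with velocities supplied, bond-
#' direction relative velocities are removed (so total linear momentum is
#' unchanged).
#'
#' @param pos n x 3 site positions; waters must be near-rigid (within ~10%).
#' @param mol_id Water molecule index per site (`NA` for ions); each molecule
#'   has sites ordered O, H, H.
#' @param mass Site masses (g/mol).
#' @param vel Optional n x 3 velocities to project.
#' @param water [water_model()] geometry targets.
#' @return List with constrained `pos` and (if given) `vel`.
#' @export
constrain_water <- function(pos, mol_id, mass, vel = NULL,
                            water = water_model()) {
  out_pos <- shake_water(pos, pos, mol_id, mass, water)
  out <- list(pos = out_pos)
  if (!is.null(vel)) out$vel <- rattle_water(out_pos, vel, mol_id, mass)
  out
}
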