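#' Steepest-descent energy minimisation
#'
#' Relaxes a freshly built configuration before dynamics: each step moves
#' every mobile site along its force with the displacement capped at
#' `max_disp`, re-applies rigid-water constraints, and backtracks (halving
#' the step) whenever the energy rises. Velocities are left untouched.
#'
#' @param config An `edl_system`.
#' @param ff A [forcefield()].
#' @param wall A [wall_model()].
#' @param n_steps Maximum descent steps (default 200).
#' @param max_disp Per-component displacement cap in A (default 0.1).
#' @param rcut Interaction cutoff passed to [total_energy_forces()].
#' @return The configuration with relaxed positions; the final energy is
#'   attached as attribute `energy`.
#' @export
minimize_config <- function(config, ff = forcefield(),
                            wall = wall_model(R_n = config$geometry$R_n),
                            n_steps = 200L, max_disp = 0.1, rcut = NULL) {
  wm <- water_model()
  has_water <- any(!is.na(config$mol_id))
  ener <- function(cfg) total_energy_forces(cfg, ff = ff, wall = wall,
                                            rcut = rcut)
  cur <- ener(config)
  step <- max_disp
  for (it in seq_len(n_steps)) {
    fmax <- max(abs(cur$forces))
    if (fmax < 1) break
    trial <- config
    disp <- cur$forces * (step / fmax)
    trial$pos <- config$pos + disp
    if (has_water)
      trial$pos <- shake_water(trial$pos, config$pos, config$mol_id,
                               config$mass, wm)
    rr <- sqrt(trial$pos[, 1L]^2 + trial$pos[, 2L]^2)
    ok <- all(rr < config$geometry$R_n - 1e-6)
    nxt <- if (ok) tryCatch(ener(trial), error = function(e) NULL) else NULL
    if (!is.null(nxt) && nxt$energy < cur$energy) {
      config <- trial; cur <- nxt
      step <- min(max_disp, step * 1.2)
    } else {
      step <- step / 2
      if (step < 1e-6) break
    }
  }
  attr(config, "energy") <- cur$energy
  config
}
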