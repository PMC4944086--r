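#' Steele 10-4-3 wall model for a cylindrical pore
#'
#' Holds the wall constants of the structureless layered-solid (Steele)
#' potential and the pore radius. Wall-fluid LJ parameters are mixed by
#' Lorentz-Berthelot from `sigma_w`/`epsilon_w` and the fluid species'
#' pure-pair parameters.
#'
#' @param R_n Pore radius in Angstrom (default 30).
#' @param Delta Interlayer spacing of the wall solid in Angstrom (default 2.709).
#' @param rho_w Wall site density in nm^-3 (default 42.76; converted to A^-3
#'   internally).
#' @param sigma_w Wall LJ size in Angstrom (default 3.0).
#' @param epsilon_w_over_kB Wall LJ well depth over Boltzmann's constant, in K
#'   (default 230).
#' @return Object of class `wall_model`.
#' @export
wall_model <- function(R_n = 30, Delta = 2.709, rho_w = 42.76,
                       sigma_w = 3.0, epsilon_w_over_kB = 230) {
  vals <- c(R_n = R_n, Delta = Delta, rho_w = rho_w, sigma_w = sigma_w,
            epsilon_w_over_kB = epsilon_w_over_kB)
  if (any(vals <= 0)) stop("wall_model constants must be strictly positive")
  structure(list(R_n = R_n, Delta = Delta,
                 rho_w = rho_w,                 # nm^-3, as conventionally quoted
                 rho_w_A3 = rho_w * 1e-3,       # A^-3, used in the energy
                 sigma_w = sigma_w,
                 epsilon_w = epsilon_w_over_kB * .kB,  # kJ/mol
                 epsilon_w_over_kB = epsilon_w_over_kB),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("<wall_model> R_n %.1f A, Delta %.3f A, rho_w %.2f nm^-3, sigma_w %.2f A, epsilon_w/kB %.0f K\n",
              x$R_n, x$Delta, x$rho_w, x$sigma_w, x$epsilon_w_over_kB))
  invisible(x)
}

#' Wall-fluid mixed LJ parameters
#'
#' Lorentz-Berthelot mixing of the wall constants with a fluid species:
#' `sigma_wf = (sigma_w + sigma)/2`, `epsilon_wf = sqrt(epsilon_w * epsilon)`.
#'
#' @param wall A [wall_model()].
#' @param species A [species_params()].
#' @return List with `sigma_wf` (A) and `epsilon_wf` (kJ/mol).
#' @export
wall_mixing <- function(wall, species) {
  if (species$epsilon < 0) stop("invalid parameter: epsilon must be >= 0")
  list(sigma_wf = (wall$sigma_w + species$sigma) / 2,
       epsilon_wf = sqrt(wall$epsilon_w * species$epsilon))
}

# shared core: z = distance from the wall surface (R_n - r), vectorised
.steele_1043 <- function(z, sigma_wf, epsilon_wf, Delta, rho_w_A3) {
  pref <- 2 * pi * rho_w_A3 * epsilon_wf * sigma_wf^2 * Delta
  pref * (0.4 * (sigma_wf / z)^10 - (sigma_wf / z)^4 -
          sigma_wf^4 / (3 * Delta * (z + 0.61 * Delta)^3))
}

.steele_1043_dz <- function(z, sigma_wf, epsilon_wf, Delta, rho_w_A3) {
  pref <- 2 * pi * rho_w_A3 * epsilon_wf * sigma_wf^2 * Delta
  pref * (-4 * sigma_wf^10 / z^11 + 4 * sigma_wf^4 / z^5 +
          sigma_wf^4 / (Delta * (z + 0.61 * Delta)^4))
}

#' Steele wall potential energy
#'
#' The 10-4-3 potential of a structureless layered wall felt by a fluid
#' particle at radial coordinate `r` inside a cylindrical pore of radius
#' `R_n`; it depends on position only through the wall distance `R_n - r`:
#' \deqn{u_{wf} = 2\pi\rho_w\epsilon_{wf}\sigma_{wf}^2\Delta\left[
#'   \tfrac{2}{5}\left(\tfrac{\sigma_{wf}}{R_n-r}\right)^{10}
#'   - \left(\tfrac{\sigma_{wf}}{R_n-r}\right)^{4}
#'   - \tfrac{\sigma_{wf}^4}{3\Delta (R_n-r+0.61\Delta)^3}\right]}
#'
#' @param r Radial coordinate(s) in Angstrom, 0 <= r < R_n.
#' @param species [species_params()] of the fluid particle.
#' @param wall [wall_model()].
#' @return Energy in kJ/mol, vectorised over `r`.
#' @seealso [steele_force()], [steele_minimum()]
#' @export
steele_energy <- function(r, species, wall) {
  if (any(r < 0)) stop("domain error: r must be >= 0")
  if (any(r >= wall$R_n)) stop("domain error: particle at or outside the wall (r >= R_n)")
  m <- wall_mixing(wall, species)
  .steele_1043(wall$R_n - r, m$sigma_wf, m$epsilon_wf, wall$Delta, wall$rho_w_A3)
}

#' Steele wall radial force
#'
#' Analytic radial force `-du/dr` on the particle; negative values pull it
#' toward the pore axis (away from the wall).
#'
#' @inheritParams steele_energy
#' @return Force in kJ/mol/A, vectorised over `r`.
#' @export
steele_force <- function(r, species, wall) {
  if (any(r < 0)) stop("domain error: r must be >= 0")
  if (any(r >= wall$R_n)) stop("domain error: particle at or outside the wall (r >= R_n)")
  m <- wall_mixing(wall, species)
  # u depends on z = R_n - r, so du/dr = -du/dz; force = -du/dr = du/dz
  .steele_1043_dz(wall$R_n - r, m$sigma_wf, m$epsilon_wf, wall$Delta, wall$rho_w_A3)
}

#' Location and depth of the Steele well
#'
#' Dense 1-D scan of the wall distance for the minimum of the 10-4-3
#' potential, refined with [stats::optimize()].
#'
#' @inheritParams steele_energy
#' @param resolution Grid spacing of the initial scan in Angstrom.
#' @return List with `wall_distance` (A, `R_n - r` at the minimum), `r` (A)
#'   and `energy` (kJ/mol).
#' @export
steele_minimum <- function(species, wall, resolution = 1e-3) {
  m <- wall_mixing(wall, species)
  f <- function(z) .steele_1043(z, m$sigma_wf, m$epsilon_wf, wall$Delta, wall$rho_w_A3)
  z <- seq(0.5 * m$sigma_wf, min(6 * m$sigma_wf, wall$R_n - 1e-6), by = resolution)
  i <- which.min(f(z))
  lo <- z[max(1L, i - 1L)]; hi <- z[min(length(z), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-9)
  list(wall_distance = opt$minimum, r = wall$R_n - opt$minimum,
       energy = opt$objective)
}
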