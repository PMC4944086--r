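#' Per-species force-field parameters
#'
#' Bundles the mass, partial charge and pure-pair Lennard-Jones parameters of
#' one species. Pure-pair means the sigma/epsilon of the like-like interaction;
#' unlike pairs are produced with [combine_lorentz_berthelot()].
#'
#' @param name Species label, one of `"O"`, `"H"`, `"Na+"`, `"Cl-"`, `"WALLQ"`
#'   or a user-defined tag.
#' @param mass Molar mass in g/mol (`NA` for frozen sites).
#' @param charge Charge in elementary charges.
#' @param sigma LJ size parameter in Angstrom (0 for LJ-inactive species).
#' @param epsilon LJ well depth in kJ/mol (0 for LJ-inactive species).
#' @return An object of class `species_params`.
#' @examples
#' species_params("Na+", mass = 22.98977, charge = +1,
#'                sigma = 2.583, epsilon = 0.4184)
#' @export
species_params <- function(name, mass, charge, sigma, epsilon) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(epsilon) && epsilon < 0)
    stop("invalid parameter: epsilon must be >= 0 for species ", name)
  if (!is.na(sigma) && sigma < 0)
    stop("invalid parameter: sigma must be >= 0 for species ", name)
  structure(list(name = name, mass = as.numeric(mass),
                 charge = as.numeric(charge),
                 sigma = as.numeric(sigma), epsilon = as.numeric(epsilon)),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species %s>  mass %.4f g/mol, charge %+.4f e, LJ sigma %.3f A, epsilon %.4f kJ/mol\n",
              x$name, x$mass, x$charge, x$sigma, x$epsilon))
  invisible(x)
}

#' Default species table
#'
#' The pure-pair LJ parameters for O, Na+ and Cl-, the SPC/E water site
#' charges and geometry-free site masses, and the frozen wall-charge species.
#' H and WALLQ carry no LJ term. Wall charges are -1 e each.
#'
#' @param file Optional path to a parameter file (see [read_forcefield_params()]);
#'   the default reads the parameter file shipped with the package.
#' @return Named list of [species_params()] objects.
#' @export
default_species <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "forcefield.par", package = "nanoporeEDL")
  read_forcefield_params(file)
}

#' Read force-field parameters from a key-value file
#'
#' The file holds one `species.<name>.<field> = <value>` entry per line
#' (fields `mass`, `charge`, `sigma`, `epsilon`); `#` starts a comment.
#'
#' @param file Path to the parameter file.
#' @return Named list of [species_params()] objects.
#' @export
read_forcefield_params <- function(file) {
  kv <- read_config(file)
  keys <- names(kv)
  sp_keys <- grep("^species\\.", keys, value = TRUE)
  if (length(sp_keys) == 0L) stop("no species entries in ", file)
  parts <- strsplit(sub("^species\\.", "", sp_keys), ".", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  fld <- vapply(parts, `[`, "", 2L)
  out <- list()
  for (s in unique(nm)) {
    get <- function(f) {
      k <- sp_keys[nm == s & fld == f]
      if (length(k) != 1L) stop("missing field ", f, " for species ", s, " in ", file)
      as.numeric(kv[[k]])
    }
    out[[s]] <- species_params(s, mass = get("mass"), charge = get("charge"),
                               sigma = get("sigma"), epsilon = get("epsilon"))
  }
  out
}

#' Lorentz-Berthelot combining rules
#'
#' Unlike-pair LJ parameters from pure-pair parameters: arithmetic mean for
#' sigma, geometric mean for epsilon.
#'
#' @param a,b [species_params()] objects (or anything with `sigma`/`epsilon`).
#' @return An object of class `pair_params` with fields `sigma` (A) and
#'   `epsilon` (kJ/mol).
#' @examples
#' na <- species_params("Na+", 22.98977, +1, 2.583, 0.4184)
#' cl <- species_params("Cl-", 35.453,  -1, 4.401, 0.4184)
#' combine_lorentz_berthelot(na, cl)  # sigma 3.492, epsilon 0.4184
#' @export
combine_lorentz_berthelot <- function(a, b) {
  if (is.na(a$epsilon) || is.na(b$epsilon) || a$epsilon < 0 || b$epsilon < 0)
    stop("invalid parameter: epsilon must be defined and >= 0")
  if (is.na(a$sigma) || is.na(b$sigma))
    stop("invalid parameter: sigma must be defined")
  structure(list(sigma = (a$sigma + b$sigma) / 2,
                 epsilon = sqrt(a$epsilon * b$epsilon)),
            class = "pair_params")
}

#' @export
print.pair_params <- function(x, ...) {
  cat(sprintf("<pair> sigma %.4f A, epsilon %.4f kJ/mol\n", x$sigma, x$epsilon))
  invisible(x)
}

#' Lennard-Jones pair energy
#'
#' \eqn{u(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}. Vectorised over `r`.
#'
#' @param r Separation(s) in Angstrom, all > 0.
#' @param pair `pair_params` (or list with `sigma`, `epsilon`).
#' @return Energy in kJ/mol.
#' @seealso [lj_force()] for the analytic radial force.
#' @export
lj_energy <- function(r, pair) {
  if (any(r <= 0)) stop("domain error: lj_energy requires r > 0")
  sr6 <- (pair$sigma / r)^6
  4 * pair$epsilon * (sr6^2 - sr6)
}

#' Lennard-Jones radial force
#'
#' \eqn{f(r) = -du/dr = 4\epsilon(12\sigma^{12}/r^{13} - 6\sigma^6/r^7)};
#' positive values push the pair apart.
#'
#' @inheritParams lj_energy
#' @return Force in kJ/mol/A.
#' @export
lj_force <- function(r, pair) {
  if (any(r <= 0)) stop("domain error: lj_force requires r > 0")
  sr6 <- (pair$sigma / r)^6
  4 * pair$epsilon * (12 * sr6^2 - 6 * sr6) / r
}

#' SPC/E water model constants
#'
#' Rigid three-site extended simple point charge model: LJ on the oxygen only,
#' partial charges -0.8476 e (O) and +0.4238 e (H), O-H bond 1.0 A, H-O-H
#' angle 109.47 degrees. The molecular net charge is exactly zero.
#'
#' @return List with `q_O`, `q_H` (e), `r_OH` (A), `angle` (degrees) and the
#'   derived rigid H-H distance `r_HH` (A).
#' @export
water_model <- function() {
  ang <- 109.47
  r_OH <- 1.0
  list(q_O = -0.8476, q_H = +0.4238, r_OH = r_OH, angle = ang,
       r_HH = 2 * r_OH * sin(ang * pi / 360))
}

#' Force-field tables for a set of species
#'
#' Precomputes the full unlike-pair sigma/epsilon matrices (Lorentz-Berthelot)
#' and per-species charge/mass lookups used by the energy and sampling
#' routines.
#'
#' @param species Named list of [species_params()]; default [default_species()].
#' @return Object of class `forcefield` with elements `species`, `sigma`,
#'   `epsilon` (matrices keyed by species name), `charge`, `mass`.
#' @export
forcefield <- function(species = default_species()) {
  nm <- names(species)
  n <- length(nm)
  sig <- matrix(0, n, n, dimnames = list(nm, nm))
  eps <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (species[[i]]$epsilon > 0 && species[[j]]$epsilon > 0) {
      p <- combine_lorentz_berthelot(species[[i]], species[[j]])
      sig[i, j] <- p$sigma; eps[i, j] <- p$epsilon
    }
  }
  structure(list(species = species,
                 sigma = sig, epsilon = eps,
                 charge = vapply(species, `[[`, 0, "charge"),
                 mass = vapply(species, `[[`, 0, "mass")),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("<forcefield> species:", paste(names(x$species), collapse = ", "), "\n")
  act <- names(x$species)[vapply(x$species, function(s) s$epsilon > 0, TRUE)]
  cat("  LJ-active:", paste(act, collapse = ", "), "\n")
  invisible(x)
}
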