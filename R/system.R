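#' Cylindrical pore geometry
#'
#' @param R_n Pore radius (A), default 30.
#' @param L_z Periodic length along the pore axis z (A), default 60.
#' @return Object of class `pore_geometry`.
#' @export
pore_geometry <- function(R_n = 30, L_z = 60) {
  if (R_n <= 0 || L_z <= 0) stop("R_n and L_z must be > 0")
  structure(list(R_n = R_n, L_z = L_z, periodic = "z"),
            class = "pore_geometry")
}

#' Build specification for an electrolyte-filled pore
#'
#' @param concentration NaCl concentration in mol/L (study conditions: 0.6,
#'   1.3, 2.0).
#' @param n_water Number of water molecules (default 1045).
#' @param n_wall_charges Number of frozen -1 e wall sites (default 8).
#' @param seed RNG seed making the build reproducible.
#' @param geometry A [pore_geometry()].
#' @return Object of class `build_spec`.
#' @export
build_spec <- function(concentration = 0.6, n_water = 1045,
                       n_wall_charges = 8, seed = 1,
                       geometry = pore_geometry()) {
  if (concentration < 0) stop("concentration must be >= 0")
  if (n_water < 0 || n_wall_charges < 0) stop("counts must be >= 0")
  structure(list(concentration = concentration, n_water = as.integer(n_water),
                 n_wall_charges = as.integer(n_wall_charges),
                 seed = as.integer(seed), geometry = geometry),
            class = "build_spec")
}

#' Electroneutral ion counts for a target concentration
#'
#' The number of NaCl pairs follows the molarity ratio against water
#' (`round(concentration * n_water / 55.345)`); each -1 e wall charge is
#' compensated by one extra Na+, so the whole system carries zero net charge.
#'
#' @param concentration mol/L.
#' @param n_water Number of water molecules.
#' @param n_wall_charges Number of -1 e wall sites.
#' @return Named integer vector `c(n_Na, n_Cl)`.
#' @examples
#' ion_counts(0.6, 1045, 8)
#' @export
ion_counts <- function(concentration, n_water, n_wall_charges) {
  if (concentration < 0 || n_water < 0 || n_wall_charges < 0)
    stop("inputs must be >= 0")
  n_pairs <- round(concentration * n_water / .water_molarity)
  c(n_Na = as.integer(n_pairs + n_wall_charges), n_Cl = as.integer(n_pairs))
}

#' Place frozen wall charges on the pore surface
#'
#' `n` sites of charge -1 e at radius exactly `R_n`, equally spaced along z
#' (spacing `L_z / n`, deterministic); azimuthal angles are drawn from the
#' seeded RNG. The implied surface charge density
#' `sigma_s = n e / (2 pi R_n L_z)` is attached as attributes (e/A^2 and
#' C/m^2).
#'
#' @param geometry A [pore_geometry()].
#' @param n Number of wall charges (>= 0).
#' @param seed RNG seed for the azimuths.
#' @return n x 3 position matrix with attributes `sigma_s` (e/A^2) and
#'   `sigma_s_C_m2`.
#' @export
place_wall_charges <- function(geometry, n, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  sigma_s <- n / (2 * pi * geometry$R_n * geometry$L_z)
  if (n == 0L) {
    out <- matrix(numeric(0), 0, 3)
  } else {
    theta <- with_seed(seed, stats::runif(n, 0, 2 * pi))
    z <- (seq_len(n) - 1) * geometry$L_z / n
    out <- cbind(geometry$R_n * cos(theta), geometry$R_n * sin(theta), z)
  }
  colnames(out) <- c("x", "y", "z")
  attr(out, "sigma_s") <- sigma_s
  attr(out, "sigma_s_C_m2") <- sigma_s * .e_per_A2_to_C_m2
  out
}

# evaluate expr with a temporarily-seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Maxwell-Boltzmann site velocities (A/fs): sd = sqrt(kB T / m) in internal
# units; kB T [kJ/mol] / m [g/mol] * 1e-4 -> (A/fs)^2
maxwell_velocities <- function(mass, T0) {
  sd <- sqrt(.kB * T0 / mass * .acc_unit)
  matrix(stats::rnorm(3 * length(mass), sd = rep(sd, 3)), ncol = 3)
}

#' Build an electroneutral electrolyte configuration in the pore
#'
#' Waters and ions are placed by rejection sampling inside `r < R_n - 1` A
#' with a minimum-separation rule of `0.8 * sigma_ij` between LJ sites
#' (relaxed later by equilibration); water molecules are rigid SPC/E with a
#' random orientation. Site velocities are Maxwell-Boltzmann at 298 K with
#' the centre-of-mass drift removed. The build is a pure function of the
#' spec, including its seed.
#'
#' @param spec A [build_spec()].
#' @param ff A [forcefield()]; default Table-based parameters.
#' @param temperature Velocity-initialisation temperature (K).
#' @param max_tries Placement attempts per particle before the build fails.
#' @return Object of class `edl_system`: per-site `species`, `pos`, `vel`,
#'   `charge`, `mass`, `mol_id` (water molecule index, `NA` for ions), frozen
#'   `wall_pos`/`wall_charge`, `geometry`, `sigma_s` (e/A^2), and the spec.
#' @export
build_system <- function(spec, ff = forcefield(), temperature = 298.0,
                         max_tries = 5000L) {
  geom <- spec$geometry
  wallq <- place_wall_charges(geom, spec$n_wall_charges, spec$seed)
  counts <- ion_counts(spec$concentration, spec$n_water, spec$n_wall_charges)
  wm <- water_model()

  with_seed(spec$seed, {
    # order: Na+, Cl-, then waters; separation is enforced on LJ sites
    lj_species <- c(rep("Na+", counts["n_Na"]), rep("Cl-", counts["n_Cl"]),
                    rep("O", spec$n_water))
    n_lj <- length(lj_species)
    lj_pos <- matrix(NA_real_, n_lj, 3)
    r_max <- geom$R_n - 1
    sig <- ff$sigma
    for (i in seq_len(n_lj)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        rr <- r_max * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cand <- c(rr * cos(th), rr * sin(th), stats::runif(1, 0, geom$L_z))
        if (i > 1L) {
          d <- sweep(lj_pos[seq_len(i - 1L), , drop = FALSE], 2, cand)
          d[, 3L] <- .min_image(d[, 3L], geom$L_z)
          dist <- sqrt(rowSums(d^2))
          min_sep <- 0.8 * sig[lj_species[seq_len(i - 1L)], lj_species[i]]
          if (any(dist < min_sep)) next
        }
        lj_pos[i, ] <- cand
        ok <- TRUE
        break
      }
      if (!ok)
        stop("packing failure: could not place species ", lj_species[i],
             " (particle ", i, ") after ", max_tries, " tries")
    }

    n_ions <- sum(counts)
    species <- lj_species[seq_len(n_ions)]
    pos <- lj_pos[seq_len(n_ions), , drop = FALSE]
    mol_id <- rep(NA_integer_, n_ions)
    if (spec$n_water > 0L) {
      o_pos <- lj_pos[n_ions + seq_len(spec$n_water), , drop = FALSE]
      for (w in seq_len(spec$n_water)) {
        hh <- random_water_orientation(o_pos[w, ], wm)
        pos <- rbind(pos, o_pos[w, , drop = FALSE], hh)
        species <- c(species, "O", "H", "H")
        mol_id <- c(mol_id, rep(w, 3L))
      }
    }
    charge <- ff$charge[species]
    mass <- ff$mass[species]
    vel <- maxwell_velocities(mass, temperature)
    # remove centre-of-mass drift
    p <- colSums(vel * mass)
    vel <- sweep(vel, 2, p / sum(mass))
    dimnames(pos) <- list(NULL, c("x", "y", "z"))

    structure(list(species = species, pos = pos, vel = vel,
                   charge = unname(charge), mass = unname(mass),
                   mol_id = mol_id,
                   wall_pos = wallq[, , drop = FALSE],
                   wall_charge = rep(-1, nrow(wallq)),
                   geometry = geom,
                   sigma_s = attr(wallq, "sigma_s"),
                   spec = spec, seed = spec$seed),
              class = "edl_system")
  })
}

# two H positions completing a rigid SPC/E water at a random orientation
random_water_orientation <- function(o, wm) {
  # random unit bisector axis and perpendicular
  repeat {
    u <- stats::rnorm(3); nu <- sqrt(sum(u^2))
    if (nu > 1e-8) { u <- u / nu; break }
  }
  repeat {
    v <- stats::rnorm(3); v <- v - sum(v * u) * u; nv <- sqrt(sum(v^2))
    if (nv > 1e-8) { v <- v / nv; break }
  }
  half <- wm$angle * pi / 360
  h1 <- o + wm$r_OH * (cos(half) * u + sin(half) * v)
  h2 <- o + wm$r_OH * (cos(half) * u - sin(half) * v)
  rbind(h1, h2)
}

#' Total charge of a configuration (mobile + wall)
#' @param config An `edl_system`.
#' @return Net charge in e.
#' @export
total_charge <- function(config) sum(config$charge) + sum(config$wall_charge)

#' @export
print.edl_system <- function(x, ...) {
  tab <- table(x$species)
  cat("<edl_system>", nrow(x$pos), "mobile sites (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  cat(sprintf("  pore R_n %.1f A, L_z %.1f A; %d wall charges (sigma_s %.4g e/A^2 = %.4g C/m^2)\n",
              x$geometry$R_n, x$geometry$L_z, length(x$wall_charge),
              x$sigma_s, x$sigma_s * .e_per_A2_to_C_m2))
  cat(sprintf("  net charge %+g e; seed %d\n", total_charge(x), x$seed))
  invisible(x)
}

#' Small analytic test configurations
#'
#' `single_ion`: one Na+ in an uncharged pore (Boltzmann-distribution
#' checks). `ideal_gas`: `n` non-interacting uncharged tracers placed
#' uniformly in the cylinder volume (flat-profile checks). `two_charge`:
#' a +1/-1 e dimer at separation `d` in a large open box (Coulomb's-law
#' checks).
#'
#' @param kind `"single_ion"`, `"ideal_gas"` or `"two_charge"`.
#' @param n Number of tracers for `ideal_gas`.
#' @param d Separation (A) for `two_charge`.
#' @param seed RNG seed.
#' @param geometry A [pore_geometry()].
#' @return An `edl_system`.
#' @export
build_fixture <- function(kind = c("single_ion", "ideal_gas", "two_charge"),
                          n = 1000L, d = 3.0, seed = 1,
                          geometry = pore_geometry()) {
  kind <- match.arg(kind)
  empty_wall <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  base <- list(wall_pos = empty_wall, wall_charge = numeric(0),
               geometry = geometry, sigma_s = 0, spec = NULL, seed = seed)
  sys <- switch(kind,
    single_ion = {
      c(list(species = "Na+", pos = matrix(c(1, 0, 0), 1, 3),
             vel = matrix(0, 1, 3), charge = 1, mass = 22.98977,
             mol_id = NA_integer_), base)
    },
    ideal_gas = {
      pos <- with_seed(seed, {
        rr <- geometry$R_n * sqrt(stats::runif(n))
        th <- stats::runif(n, 0, 2 * pi)
        cbind(rr * cos(th), rr * sin(th), stats::runif(n, 0, geometry$L_z))
      })
      c(list(species = rep("X", n), pos = pos, vel = matrix(0, n, 3),
             charge = rep(0, n), mass = rep(1, n),
             mol_id = rep(NA_integer_, n)), base)
    },
    two_charge = {
      g <- pore_geometry(R_n = 500, L_z = 1000)
      b <- base; b$geometry <- g
      c(list(species = c("Na+", "Cl-"),
             pos = rbind(c(250, 250, 500), c(250, 250, 500 + d)),
             vel = matrix(0, 2, 3), charge = c(1, -1),
             mass = c(22.98977, 35.453),
             mol_id = rep(NA_integer_, 2)), b)
    })
  sys$pos <- matrix(sys$pos, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  structure(sys, class = "edl_system")
}
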