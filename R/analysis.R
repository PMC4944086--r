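# Trajectory analysis: radial concentration profiles, surface-charge
# screening factor, radial electrostatic potential, peak reporting.

.radial_edges <- function(R_n, bin_width) {
  edges <- seq(0, R_n, by = bin_width)
  if (edges[length(edges)] < R_n) edges <- c(edges, R_n)
  edges
}

#' Radial concentration profile of one species
#'
#' Per-frame counts of the species' sites binned by the radial coordinate
#' r = sqrt(x^2 + y^2), averaged over frames, divided by the cylindrical
#' shell volume pi (r_out^2 - r_in^2) L_z, and converted to mol/L. The
#' closure identity sum(C * V_shell) * N_A = mean count per frame holds to
#' round-off.
#'
#' @param traj An `edl_trajectory`.
#' @param species Species tag to profile (e.g. `"Na+"`).
#' @param bin_width Radial bin width in A (default 0.25).
#' @return Object of class `radial_profile` with `r_mid`, `r_edges` (A),
#'   `conc` (mol/L), `stderr` (frame-to-frame standard error, mol/L),
#'   `mean_count`, `shell_volume` (A^3), `species`, `n_frames`, `geometry`.
#' @export
radial_density <- function(traj, species, bin_width = 0.25) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (length(traj$frames) == 0L) stop("empty trajectory")
  geom <- traj$geometry
  edges <- .radial_edges(geom$R_n, bin_width)
  nb <- length(edges) - 1L
  sel <- traj$species == species
  nf <- length(traj$frames)
  counts <- matrix(0, nf, nb)
  if (any(sel)) {
    for (f in seq_len(nf)) {
      p <- traj$frames[[f]]
      r <- sqrt(p[sel, 1L]^2 + p[sel, 2L]^2)
      counts[f, ] <- tabulate(findInterval(r, edges, rightmost.closed = TRUE,
                                           all.inside = TRUE), nbins = nb)
    }
  }
  vshell <- pi * (edges[-1L]^2 - edges[-length(edges)]^2) * geom$L_z
  mean_count <- colMeans(counts)
  conc <- mean_count / vshell * .conc_per_A3
  se <- if (nf > 1L) apply(counts, 2L, stats::sd) / sqrt(nf) / vshell * .conc_per_A3
        else rep(NA_real_, nb)
  structure(list(r_mid = (edges[-1L] + edges[-length(edges)]) / 2,
                 r_edges = edges, conc = conc, stderr = se,
                 mean_count = mean_count, shell_volume = vshell,
                 species = species, n_frames = nf, geometry = geom),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s: %d bins of %.2f A over %d frames; peak %.3f mol/L at r %.2f A\n",
              x$species, length(x$conc), diff(x$r_edges[1:2]), x$n_frames,
              max(x$conc), x$r_mid[which.max(x$conc)]))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, ...,
                                xlab = "wall distance R_n - r (A)",
                                ylab = "concentration (mol/L)") {
  graphics::plot(x$geometry$R_n - x$r_mid, x$conc, type = "l",
                 xlab = xlab, ylab = ylab,
                 main = paste(x$species, "radial concentration"), ...)
  invisible(x)
}

#' Surface-charge screening factor
#'
#' Cumulative mobile net charge per unit wall area from the wall inward,
#' normalised by the surface charge density:
#' \deqn{S_f(r) = \frac{1}{\sigma_s}\int_r^{R_n} F\,[C_{Na}(r') -
#'   C_{Cl}(r')]\,\frac{r'}{R_n}\,dr'}
#' The factor r'/R_n is the cylindrical area Jacobian expressing mobile
#' charge per unit wall area; with it, global electroneutrality makes
#' S_f(0) = 1 exactly and S_f(R_n) = 0 by construction. `planar = TRUE`
#' drops the Jacobian (literal planar form, which does not close to 1 in a
#' cylinder). Each histogram bin's shell is integrated exactly
#' (piecewise-constant concentration), so the closure holds to round-off.
#' S_f(r) > 1 means the surface charge is overscreened between the wall and
#' r.
#'
#' @param na_profile,cl_profile [radial_density()] profiles of the
#'   counterion (Na+) and coion (Cl-) on identical bins.
#' @param sigma_s Surface charge density magnitude in e/A^2 (> 0); the value
#'   recorded by [place_wall_charges()].
#' @param planar Drop the cylindrical Jacobian (default `FALSE`).
#' @return Object of class `screening_profile` with `r` (bin edges, A),
#'   `S_f`, `sigma_s` (e/A^2), `sigma_s_C_m2`, `planar`.
#' @export
screening_factor <- function(na_profile, cl_profile, sigma_s,
                             planar = FALSE) {
  if (!isTRUE(all.equal(na_profile$r_edges, cl_profile$r_edges)))
    stop("mismatched binning between profiles")
  if (is.null(sigma_s) || !is.finite(sigma_s) || sigma_s <= 0)
    stop("sigma_s must be a positive surface charge density (e/A^2)")
  edges <- na_profile$r_edges
  R_n <- na_profile$geometry$R_n
  ## net charge number density per bin in e/A^3
  rho <- (na_profile$conc - cl_profile$conc) / .conc_per_A3
  r_in <- edges[-length(edges)]; r_out <- edges[-1L]
  contrib <- if (planar) rho * (r_out - r_in)
             else rho * (r_out^2 - r_in^2) / (2 * R_n)
  S_edge <- rev(cumsum(rev(contrib))) / sigma_s
  structure(list(r = edges, S_f = c(S_edge, 0),
                 sigma_s = sigma_s,
                 sigma_s_C_m2 = sigma_s * .e_per_A2_to_C_m2,
                 planar = planar),
            class = "screening_profile")
}

#' @export
print.screening_profile <- function(x, ...) {
  cat(sprintf("<screening_profile>%s S_f(0) = %.4f, max S_f = %.4f; sigma_s %.4g e/A^2\n",
              if (x$planar) " [planar]" else "", x$S_f[1L], max(x$S_f), x$sigma_s))
  invisible(x)
}

#' @export
plot.screening_profile <- function(x, ..., xlab = "r (A)", ylab = "S_f(r)") {
  graphics::plot(x$r, x$S_f, type = "l", xlab = xlab, ylab = ylab,
                 main = "screening factor", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Radius where the surface charge is first overscreened
#'
#' Scanning inward from the wall, the largest radius at which S_f reaches 1.
#' Returns the axis (r = 0) when the screening never exceeds unity before
#' closure.
#'
#' @param sp A `screening_profile`.
#' @return List with `r` (A) and `wall_distance` (A).
#' @export
first_overscreening_radius <- function(sp) {
  R_n <- max(sp$r)
  cross <- which(sp$S_f >= 1)
  r <- if (length(cross)) max(sp$r[cross]) else 0
  list(r = r, wall_distance = R_n - r)
}

#' Radial electrostatic potential profile
#'
#' Coulomb's law with point-charge superposition, referenced to the pore
#' axis: for a probe at radius r,
#' \deqn{\phi(r) = C \sum_i q_i\left(\frac{1}{|x - x_i|} -
#'   \frac{1}{|x_0 - x_i|}\right)}
#' summed over all mobile charges and frozen wall charges with the
#' minimum-image convention along z, averaged over azimuthal and axial probe
#' positions and over frames, and converted to volts. phi(r0) = 0 exactly by
#' construction (r0 on the axis). In implicit-solvent trajectories the sum
#' is divided by the continuum dielectric constant. Probe samples closer
#' than 0.5 A to any charge are excluded and counted.
#'
#' @param traj An `edl_trajectory`.
#' @param bin_width Radial spacing of field points (A, default 0.25).
#' @param n_azimuth,n_axial Number of azimuthal (default 64) and axial
#'   (default 8) probe positions per radius.
#' @param frame_stride Use every `frame_stride`-th frame (default 1).
#' @param radii Optional explicit field-point radii (A) overriding the
#'   `bin_width` grid; `0` evaluates at the reference itself (exactly 0 V).
#' @return Object of class `potential_profile` with `r_mid` (A), `phi` (V),
#'   `stderr` (V, over frames), `n_excluded`, `reference` = 0 at r = 0.
#' @export
radial_potential <- function(traj, bin_width = 0.25, n_azimuth = 64L,
                             n_axial = 8L, frame_stride = 1L, radii = NULL) {
  if (length(traj$frames) == 0L) stop("empty trajectory")
  geom <- traj$geometry
  Lz <- geom$L_z
  r_mid <- if (!is.null(radii)) radii else {
    edges <- .radial_edges(geom$R_n, bin_width)
    (edges[-1L] + edges[-length(edges)]) / 2
  }
  theta <- 2 * pi * (seq_len(n_azimuth) - 1L) / n_azimuth
  zs <- Lz * (seq_len(n_axial) - 0.5) / n_axial
  f_idx <- seq(1L, length(traj$frames), by = frame_stride)
  nf <- length(f_idx)
  scale <- .k_coulomb * .volt_per_kJmol_e / traj$dielectric

  phi_frames <- matrix(NA_real_, nf, length(r_mid))
  n_excluded <- 0L
  axis_probe <- cbind(0, 0, zs)
  for (fi in seq_len(nf)) {
    p <- traj$frames[[f_idx[fi]]]
    qpos <- rbind(p, traj$wall_pos)
    qs <- c(traj$charge, traj$wall_charge)
    nz <- qs != 0
    qpos <- qpos[nz, , drop = FALSE]; qs <- qs[nz]
    if (length(qs) == 0L) { phi_frames[fi, ] <- 0; next }
    ref_vals <- .probe_potential(axis_probe, qpos, qs, Lz)
    n_excluded <- n_excluded + ref_vals$n_excluded
    ref <- mean(ref_vals$phi, na.rm = TRUE)
    for (b in seq_along(r_mid)) {
      pr <- cbind(rep(r_mid[b] * cos(theta), times = n_axial),
                  rep(r_mid[b] * sin(theta), times = n_axial),
                  rep(zs, each = n_azimuth))
      vals <- .probe_potential(pr, qpos, qs, Lz)
      n_excluded <- n_excluded + vals$n_excluded
      phi_frames[fi, b] <- mean(vals$phi, na.rm = TRUE) - ref
    }
  }
  phi <- colMeans(phi_frames, na.rm = TRUE) * scale
  se <- if (nf > 1L) apply(phi_frames, 2L, stats::sd, na.rm = TRUE) / sqrt(nf) * scale
        else rep(NA_real_, length(r_mid))
  structure(list(r_mid = r_mid, phi = phi, stderr = se,
                 n_excluded = n_excluded, n_frames = nf,
                 geometry = geom, reference_r = 0),
            class = "potential_profile")
}

# raw (unit-scaled later) potential sum at probe points; excludes probes
# within 0.5 A of any charge
.probe_potential <- function(probes, qpos, qs, Lz) {
  dx <- outer(probes[, 1L], qpos[, 1L], `-`)
  dy <- outer(probes[, 2L], qpos[, 2L], `-`)
  dz <- outer(probes[, 3L], qpos[, 3L], `-`)
  dz <- dz - Lz * round(dz / Lz)
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  bad <- rowSums(r < 0.5) > 0L
  phi <- as.vector((1 / r) %*% qs)
  phi[bad] <- NA_real_
  list(phi = phi, n_excluded = sum(bad))
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf("<potential_profile> %d radii over %d frames; phi range [%.4g, %.4g] V; %d probe samples excluded\n",
              length(x$r_mid), x$n_frames, min(x$phi, na.rm = TRUE),
              max(x$phi, na.rm = TRUE), x$n_excluded))
  invisible(x)
}

#' @export
plot.potential_profile <- function(x, ..., xlab = "r (A)", ylab = "phi (V)") {
  graphics::plot(x$r_mid, x$phi, type = "l", xlab = xlab, ylab = ylab,
                 main = "radial potential (axis reference)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Locate the density peak and first valley of a radial profile
#'
#' Reports the global maximum as a distance from the wall (R_n minus the
#' bin-centre radius) together with the first local minimum inward of the
#' peak (toward the axis), supporting statements about coion peaks sitting
#' in the counterion's first density valley.
#'
#' @param profile A [radial_density()] profile with at least 3 bins.
#' @return Object of class `peak_report`: `peak_r`, `wall_distance`,
#'   `height` (mol/L), `valley_r`, `valley_wall_distance`, `valley_height`
#'   (all `NA` with `no_peak = TRUE` for an all-zero profile; valley fields
#'   `NA` for a boundary peak with no interior minimum).
#' @export
locate_peaks <- function(profile) {
  if (length(profile$conc) < 3L) stop("need at least 3 bins")
  R_n <- profile$geometry$R_n
  if (all(profile$conc == 0)) {
    return(structure(list(no_peak = TRUE, peak_r = NA_real_,
                          wall_distance = NA_real_, height = NA_real_,
                          valley_r = NA_real_,
                          valley_wall_distance = NA_real_,
                          valley_height = NA_real_),
                     class = "peak_report"))
  }
  imax <- which.max(profile$conc)
  c_ <- profile$conc
  valley <- NA_integer_
  if (imax > 2L) {
    for (k in (imax - 1L):2L) {
      if (c_[k] <= c_[k - 1L] && c_[k] <= c_[k + 1L]) { valley <- k; break }
    }
  }
  structure(list(no_peak = FALSE,
                 peak_r = profile$r_mid[imax],
                 wall_distance = R_n - profile$r_mid[imax],
                 height = c_[imax],
                 valley_r = if (is.na(valley)) NA_real_ else profile$r_mid[valley],
                 valley_wall_distance = if (is.na(valley)) NA_real_ else R_n - profile$r_mid[valley],
                 valley_height = if (is.na(valley)) NA_real_ else c_[valley]),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (x$no_peak) { cat("<peak_report> no peak (all-zero profile)\n"); return(invisible(x)) }
  cat(sprintf("<peak_report> peak %.3f mol/L at r %.2f A (%.2f A from wall)",
              x$height, x$peak_r, x$wall_distance))
  if (!is.na(x$valley_r))
    cat(sprintf("; first valley %.3f mol/L at %.2f A from wall",
                x$valley_height, x$valley_wall_distance))
  cat("\n")
  invisible(x)
}
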