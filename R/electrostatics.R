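# Point-charge electrostatics: direct sums, reaction-field cutoff, and 3D
# Ewald summation (tin-foil boundary). Internal unit of energy is kJ/mol with
# the Coulomb constant 1389.35458 kJ A / (mol e^2).

.min_image <- function(d, L) d - L * round(d / L)

# displacement matrix helpers: pos is N x 3; periodic z only unless box given
.pair_vectors <- function(pos, Lz = NULL) {
  n <- nrow(pos)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pos[ij[, 2L], , drop = FALSE] - pos[ij[, 1L], , drop = FALSE]
  if (!is.null(Lz)) d[, 3L] <- .min_image(d[, 3L], Lz)
  list(i = ij[, 1L], j = ij[, 2L], d = d,
       r = sqrt(rowSums(d * d)))
}

#' Direct Coulomb energy of a set of point charges
#'
#' Plain pairwise \eqn{k q_i q_j / (\epsilon_r r)} sum, optionally with the
#' minimum-image convention along z. Used as the non-periodic reference and
#' by the implicit-solvent sampler.
#'
#' @param pos N x 3 matrix of positions (A).
#' @param q Numeric vector of charges (e).
#' @param Lz Periodic length along z (A), or `NULL` for an open system.
#' @param dielectric Relative dielectric constant (1 for explicit solvent).
#' @param exclude Optional two-column matrix of pair indices to exclude
#'   (e.g. intramolecular water pairs).
#' @return Energy in kJ/mol.
#' @export
coulomb_energy_direct <- function(pos, q, Lz = NULL, dielectric = 1,
                                  exclude = NULL) {
  if (nrow(pos) < 2L) return(0)
  pv <- .pair_vectors(pos, Lz)
  keep <- rep(TRUE, length(pv$r))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- paste(pmin(pv$i, pv$j), pmax(pv$i, pv$j))
    exk <- paste(pmin(exclude[, 1L], exclude[, 2L]),
                 pmax(exclude[, 1L], exclude[, 2L]))
    keep <- !(key %in% exk)
  }
  sum(.k_coulomb * q[pv$i][keep] * q[pv$j][keep] / (dielectric * pv$r[keep]))
}

# Reaction-field pair potential with conducting (eps_RF = Inf) boundary:
# u(r) = k q q [1/r + r^2/(2 rc^3) - 3/(2 rc)], zero value and slope at rc.
.rf_energy <- function(r, qq, rc, dielectric = 1) {
  out <- numeric(length(r))
  in_rc <- r < rc
  out[in_rc] <- .k_coulomb * qq[in_rc] / dielectric *
    (1 / r[in_rc] + r[in_rc]^2 / (2 * rc^3) - 3 / (2 * rc))
  out
}

# magnitude of -du/dr for the RF potential (positive = repulsive for qq>0)
.rf_force <- function(r, qq, rc, dielectric = 1) {
  out <- numeric(length(r))
  in_rc <- r < rc
  out[in_rc] <- .k_coulomb * qq[in_rc] / dielectric *
    (1 / r[in_rc]^2 - r[in_rc] / rc^3)
  out
}

#' Ewald summation energy (and forces) for a 3D-periodic box
#'
#' Standard real/reciprocal split with tin-foil (conducting) boundary
#' conditions. The conditionally convergent lattice sum is made absolutely
#' convergent by the complementary-error-function screening; the system must
#' be exactly charge-neutral.
#'
#' @param pos N x 3 matrix of positions (A).
#' @param q Charges (e); must sum to (numerically) zero.
#' @param box Length-3 vector of box edges (A); orthorhombic.
#' @param alpha Splitting parameter (1/A); default `3.5 / rcut`.
#' @param rcut Real-space cutoff (A); must not exceed half the smallest box
#'   edge. Default `min(box)/2`.
#' @param kmax Integer reciprocal-space cutoff per dimension; default chosen
#'   so that the neglected Gaussian weight is below ~1e-6.
#' @param forces If `TRUE` also return the N x 3 force matrix (kJ/mol/A).
#' @param exclude Optional two-column matrix of intramolecular pair indices
#'   whose direct interaction is removed (the screened complement is
#'   subtracted, standard exclusion correction).
#' @return Energy in kJ/mol, or `list(energy, forces)` when `forces = TRUE`.
#' @export
ewald_energy <- function(pos, q, box, alpha = NULL, rcut = NULL, kmax = NULL,
                         forces = FALSE, exclude = NULL) {
  stopifnot(length(box) == 3L, all(box > 0))
  n <- nrow(pos)
  if (abs(sum(q)) > 1e-8)
    stop("ewald requires an exactly neutral system (tin-foil boundary)")
  if (is.null(rcut)) rcut <- min(box) / 2
  if (rcut > min(box) / 2 + 1e-9)
    stop("cutoff larger than half the minimum periodic dimension")
  if (is.null(alpha)) alpha <- 3.5 / rcut
  if (is.null(kmax)) kmax <- ceiling(2 * 3.5 * alpha * max(box) / (2 * pi))
  V <- prod(box)

  Fmat <- if (forces) matrix(0, n, 3) else NULL

  ## real space (minimum image; valid because rcut <= min(box)/2); excluded
  ## pairs are skipped here and their screened complement removed below
  e_real <- 0
  if (n > 1L) {
    pv <- .pair_vectors(pos, Lz = NULL)
    for (k in 1:3) pv$d[, k] <- .min_image(pv$d[, k], box[k])
    r <- sqrt(rowSums(pv$d^2))
    sel <- r < rcut
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      key <- paste(pv$i, pv$j)
      sel <- sel & !(key %in% paste(exclude[, 1L], exclude[, 2L]))
    }
    if (any(sel)) {
      ri <- r[sel]; qq <- q[pv$i[sel]] * q[pv$j[sel]]
      e_real <- sum(.k_coulomb * qq * erfc_(alpha * ri) / ri)
      if (forces) {
        fmag <- .k_coulomb * qq * (erfc_(alpha * ri) / ri^2 +
                2 * alpha / sqrt(pi) * exp(-(alpha * ri)^2) / ri)
        fv <- pv$d[sel, , drop = FALSE] * (fmag / ri)   # force on j (d = xj - xi)
        for (k in 1:3) {
          Fmat[, k] <- Fmat[, k] +
            tabulate_add(pv$j[sel], fv[, k], n) - tabulate_add(pv$i[sel], fv[, k], n)
        }
      }
    }
  }

  ## reciprocal space
  g <- expand.grid(nx = -kmax:kmax, ny = -kmax:kmax, nz = -kmax:kmax)
  g <- g[!(g$nx == 0 & g$ny == 0 & g$nz == 0), , drop = FALSE]
  kvec <- cbind(2 * pi * g$nx / box[1], 2 * pi * g$ny / box[2],
                2 * pi * g$nz / box[3])
  k2 <- rowSums(kvec^2)
  keep <- k2 <= (2 * 3.5 * alpha)^2
  kvec <- kvec[keep, , drop = FALSE]; k2 <- k2[keep]
  A <- exp(-k2 / (4 * alpha^2)) / k2
  ph <- pos %*% t(kvec)                  # N x K phases
  C <- colSums(q * cos(ph)); D <- colSums(q * sin(ph))
  e_recip <- .k_coulomb * (2 * pi / V) * sum(A * (C^2 + D^2))
  if (forces) {
    # F_i = k (4 pi / V) q_i sum_k A_k k (C sin_i - D cos_i)
    W <- sin(ph) * rep(A * C, each = n) - cos(ph) * rep(A * D, each = n)
    for (k in 1:3)
      Fmat[, k] <- Fmat[, k] + .k_coulomb * (4 * pi / V) * q * (W %*% kvec[, k])
  }

  ## self term
  e_self <- -.k_coulomb * alpha / sqrt(pi) * sum(q^2)

  ## exclusion correction: remove the full periodic interaction of excluded
  ## pairs by subtracting erf(alpha r)/r (their erfc part was never added)
  e_excl <- 0
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    d <- pos[exclude[, 2L], , drop = FALSE] - pos[exclude[, 1L], , drop = FALSE]
    for (k in 1:3) d[, k] <- .min_image(d[, k], box[k])
    r <- sqrt(rowSums(d^2))
    qq <- q[exclude[, 1L]] * q[exclude[, 2L]]
    e_excl <- -sum(.k_coulomb * qq * erf_(alpha * r) / r)
    if (forces) {
      fmag <- -.k_coulomb * qq * (erf_(alpha * r) / r^2 -
              2 * alpha / sqrt(pi) * exp(-(alpha * r)^2) / r)
      fv <- d * (fmag / r)
      for (k in 1:3) {
        Fmat[, k] <- Fmat[, k] +
          tabulate_add(exclude[, 2L], fv[, k], n) -
          tabulate_add(exclude[, 1L], fv[, k], n)
      }
    }
  }

  e <- e_real + e_recip + e_self + e_excl
  if (forces) list(energy = e, forces = Fmat) else e
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# sum `val` into an n-vector at positions idx (duplicated indices allowed)
tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Total electrostatic energy of a configuration
#'
#' Coulomb energy of all mobile charges plus the frozen wall charges of an
#' [build_system()] configuration. `method = "ewald"` embeds the z-periodic
#' pore in a 3D-periodic box with lateral vacuum padding (box edge `4 R_n`)
#' and requires exact neutrality; `method = "cutoff_rf"` uses a cutoff with
#' conducting reaction-field damping (fast mode, zero value and slope at the
#' cutoff). Intramolecular water pairs are excluded in both modes.
#'
#' @param config An `edl_system` configuration.
#' @param method `"ewald"` or `"cutoff_rf"`.
#' @param rcut Cutoff for `cutoff_rf` (A); default `min(L_z, 2 R_n)/2`.
#' @param dielectric Relative dielectric constant (default 1).
#' @return Energy in kJ/mol.
#' @export
electrostatic_energy <- function(config, method = c("cutoff_rf", "ewald"),
                                 rcut = NULL, dielectric = 1) {
  method <- match.arg(method)
  pos <- rbind(config$pos, config$wall_pos)
  q <- c(config$charge, config$wall_charge)
  if (length(q) == 0L || all(q == 0)) return(0)
  Lz <- config$geometry$L_z
  excl <- water_exclusions(config$mol_id)
  if (method == "ewald") {
    box <- c(4 * config$geometry$R_n, 4 * config$geometry$R_n, Lz)
    ewald_energy(pos, q, box, exclude = excl) / dielectric
  } else {
    if (is.null(rcut)) rcut <- min(Lz, 2 * config$geometry$R_n) / 2
    if (rcut > Lz / 2 + 1e-9)
      stop("cutoff larger than half the minimum periodic dimension")
    pv <- .pair_vectors(pos, Lz)
    keep <- rep(TRUE, length(pv$r))
    if (!is.null(excl) && nrow(excl) > 0L) {
      key <- paste(pv$i, pv$j); exk <- paste(excl[, 1L], excl[, 2L])
      keep <- !(key %in% exk)
    }
    sum(.rf_energy(pv$r[keep], q[pv$i][keep] * q[pv$j][keep], rcut, dielectric))
  }
}

# intramolecular (same rigid water) site pairs as an index matrix, i < j
water_exclusions <- function(mol_id) {
  if (is.null(mol_id) || all(is.na(mol_id))) return(NULL)
  ids <- unique(mol_id[!is.na(mol_id)])
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    s <- which(!is.na(mol_id) & mol_id == ids[k])
    cmb <- utils::combn(sort(s), 2L)
    out[[k]] <- cbind(cmb[1L, ], cmb[2L, ])
  }
  do.call(rbind, out)
}
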