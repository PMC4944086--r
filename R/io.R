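# Plain-text I/O: flat key-value config files, multi-frame XYZ, PDB, TSV
# logs. All writes go through an atomic write-temp-then-rename path.

#' Atomically write a text file
#'
#' The writer function receives a temporary path in the target directory;
#' the file is renamed into place only after the writer returns, so partial
#' outputs never masquerade as complete files.
#'
#' @param path Final path.
#' @param writer Function of one argument (the temporary path).
#' @return `path`, invisibly.
#' @export
atomic_write <- function(path, writer) {
  tmp <- tempfile(basename(path), dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; keys may be
#' dotted. Malformed lines raise an error naming the line number.
#'
#' @param path File path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.+-]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed config line %d in %s: '%s'", i, path, lines[i]))
    out[[m[2L]]] <- trimws(m[3L])
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param kv Named list (values coerced with `format()`).
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_config <- function(kv, path) {
  lines <- vapply(names(kv),
                  function(k) sprintf("%s = %s", k, format(kv[[k]], digits = 17)),
                  "")
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

.species_element <- c("O" = "O", "H" = "H", "Na+" = "Na", "Cl-" = "Cl",
                      "WALLQ" = "Wq", "X" = "X")

#' Write a configuration or trajectory as (multi-frame) XYZ
#'
#' Frames are self-delimiting (count line, comment line, then one
#' `species x y z` row per site); species tags are written verbatim so the
#' package's [read_xyz()] round-trips them. Wall-charge sites are appended
#' after the mobile sites in every frame.
#'
#' @param x An `edl_system` or `edl_trajectory`.
#' @param path Destination file.
#' @param comment Extra text for the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "") {
  frames <- if (inherits(x, "edl_trajectory")) x$frames else list(x$pos)
  species <- x$species
  wall_n <- nrow(x$wall_pos)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    for (f in seq_along(frames)) {
      p <- rbind(frames[[f]], x$wall_pos)
      sp <- c(species, rep("WALLQ", wall_n))
      writeLines(as.character(nrow(p)), con)
      writeLines(sprintf("frame=%d seed=%d %s", f,
                         if (is.null(x$seed)) NA_integer_ else x$seed, comment), con)
      writeLines(sprintf("%-6s %14.7f %14.7f %14.7f", sp, p[, 1L], p[, 2L], p[, 3L]),
                 con)
    }
  })
}

#' Read a (multi-frame) XYZ file written by the package
#'
#' @param path File path.
#' @return List of frames, each `list(species, pos)`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    frames[[length(frames) + 1L]] <- list(
      species = vapply(toks, `[`, "", 1L),
      pos = matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                   ncol = 3, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y", "z"))))
    i <- i + 2L + n
  }
  frames
}

#' Write a configuration as PDB
#'
#' Minimal ATOM records: waters as residue `WAT`, ions as `ION`, wall
#' charges as `WLQ`; the pore axis is z. Coordinates wider than the PDB
#' fixed columns are not expected at pore scale.
#'
#' @param config An `edl_system`.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(config, path) {
  sp <- c(config$species, rep("WALLQ", nrow(config$wall_pos)))
  p <- rbind(config$pos, config$wall_pos)
  res <- ifelse(sp %in% c("O", "H"), "WAT", ifelse(sp == "WALLQ", "WLQ", "ION"))
  el <- .species_element[sp]
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(sprintf("REMARK   seed %d sigma_s %.6g e/A^2",
                       if (is.null(config$seed)) NA_integer_ else config$seed,
                       config$sigma_s), con)
    resid <- c(if (length(config$mol_id)) ifelse(is.na(config$mol_id), 0L, config$mol_id) else integer(0),
               rep(0L, nrow(config$wall_pos)))
    writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_along(sp) %% 100000L, substr(el, 1, 4), res,
                       (resid %% 10000L), p[, 1L], p[, 2L], p[, 3L],
                       substr(el, 1, 2)), con)
    writeLines("END", con)
  })
}

#' Write an energy/temperature log as TSV
#'
#' Columns: frame, temperature (K), potential (kJ/mol), total (kJ/mol).
#'
#' @param traj An `edl_trajectory`.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_energy_log <- function(traj, path) {
  df <- data.frame(frame = seq_along(traj$frames),
                   temperature_K = traj$temperature,
                   potential_kJmol = traj$potential,
                   total_kJmol = traj$total_energy)
  atomic_write(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Write a profile as TSV
#'
#' `radial_profile` gives columns r, wall_distance, value, stderr;
#' `screening_profile` gives r, S_f; `potential_profile` gives r, phi_V,
#' stderr.
#'
#' @param x A profile object from the analysis module.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  df <- if (inherits(x, "radial_profile")) {
    data.frame(r_A = x$r_mid, wall_distance_A = x$geometry$R_n - x$r_mid,
               conc_mol_L = x$conc, stderr = x$stderr)
  } else if (inherits(x, "screening_profile")) {
    data.frame(r_A = x$r, S_f = x$S_f)
  } else if (inherits(x, "potential_profile")) {
    data.frame(r_A = x$r_mid, phi_V = x$phi, stderr = x$stderr)
  } else stop("unsupported profile class")
  atomic_write(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Write trajectory + metadata, and read them back
#'
#' The trajectory is stored as multi-frame XYZ next to a flat key-value
#' metadata file (`<path>.meta`) holding the geometry, surface charge
#' density, dielectric constant, seed and mode, which
#' [read_trajectory()] uses to reconstruct an analysable `edl_trajectory`.
#'
#' @param traj An `edl_trajectory`.
#' @param path XYZ destination; metadata goes to `paste0(path, ".meta")`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_xyz(traj, path)
  kv <- list(R_n = traj$geometry$R_n, L_z = traj$geometry$L_z,
             sigma_s = traj$sigma_s, dielectric = traj$dielectric,
             seed = traj$seed, mode = traj$mode,
             n_wall = length(traj$wall_charge))
  write_config(kv, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trajectory
#' @param ff A [forcefield()] used to re-assign charges from species tags.
#' @export
read_trajectory <- function(path, ff = forcefield()) {
  meta <- read_config(paste0(path, ".meta"))
  frames_raw <- read_xyz(path)
  if (length(frames_raw) == 0L) stop("no frames in ", path)
  sp_all <- frames_raw[[1L]]$species
  is_wall <- sp_all == "WALLQ"
  species <- sp_all[!is_wall]
  wall_pos <- frames_raw[[1L]]$pos[is_wall, , drop = FALSE]
  frames <- lapply(frames_raw, function(f) f$pos[!is_wall, , drop = FALSE])
  geom <- pore_geometry(R_n = as.numeric(meta$R_n), L_z = as.numeric(meta$L_z))
  mol_id <- rep(NA_integer_, length(species))
  structure(list(frames = frames, species = species,
                 charge = unname(ff$charge[species]),
                 mass = unname(ff$mass[species]), mol_id = mol_id,
                 wall_pos = wall_pos,
                 wall_charge = rep(-1, nrow(wall_pos)),
                 geometry = geom,
                 sigma_s = as.numeric(meta$sigma_s),
                 temperature = rep(NA_real_, length(frames)),
                 potential = rep(NA_real_, length(frames)),
                 total_energy = rep(NA_real_, length(frames)),
                 mode = meta$mode,
                 dielectric = as.numeric(meta$dielectric),
                 seed = as.integer(meta$seed), spec = NULL,
                 acceptance = NA_real_),
            class = "edl_trajectory")
}
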