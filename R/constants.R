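# Internal unit system: length A, energy kJ/mol, mass g/mol, time fs, charge e.

#' Physical constants used by the package
#'
#' Named vector of the constants that fix the internal unit system
#' (Angstrom, kJ/mol, g/mol, fs, elementary charge).
#'
#' @return Named numeric vector with elements `kB` (kJ/mol/K), `k_coulomb`
#'   (kJ A / (mol e^2)), `N_A` (1/mol), `water_molarity` (mol/L),
#'   `conc_per_A3` (mol/L per A^-3), `volt_per_kJmol_e` (V per kJ/mol/e)
#'   and `e_per_A2_to_C_m2` (C/m^2 per e/A^2).
#' @export
edl_constants <- function() {
  c(kB = 0.0083144621,
    k_coulomb = 1389.35458,
    N_A = 6.02214076e23,
    water_molarity = 55.345,
    conc_per_A3 = 1e27 / 6.02214076e23,
    volt_per_kJmol_e = 1 / 96.48533212,
    e_per_A2_to_C_m2 = 16.0217663)
}

.kB <- 0.0083144621
.k_coulomb <- 1389.35458
.water_molarity <- 55.345
.conc_per_A3 <- 1e27 / 6.02214076e23     # A^-3 -> mol/L
.volt_per_kJmol_e <- 1 / 96.48533212     # kJ/(mol e) -> V
.e_per_A2_to_C_m2 <- 16.0217663

# fs^2 conversion: F [kJ/mol/A] / m [g/mol] -> acceleration in A/fs^2
# 1 kJ/mol/A / (1 g/mol) = 1e-4 A/fs^2
.acc_unit <- 1e-4
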