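Package: nanoporeEDL
Title: Molecular Simulation of Electric Double Layers in Charged Cylindrical Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, simulates and analyses NaCl electrolyte confined in a
    negatively charged cylindrical nanopore. Provides a Lennard-Jones force
    field with Lorentz-Berthelot combining rules, the Steele 10-4-3 wall
    potential, point-charge electrostatics (Ewald summation and a
    reaction-field cutoff mode), a rigid three-site SPC/E water model, a
    velocity-Verlet molecular-dynamics integrator with Berendsen
    thermostatting and rigid-water constraints, and an implicit-solvent
    Metropolis Monte-Carlo sampler. Analysis routines compute radial ion
    concentration profiles, the surface-charge screening factor, and the
    radial electrostatic potential, with peak-location reporting for
    electric-double-layer structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
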