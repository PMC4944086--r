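# Default force-field parameters.
# Pure-pair LJ rows (sigma in A, epsilon in kJ/mol); unlike pairs follow
# Lorentz-Berthelot. Water is rigid SPC/E: LJ on O only, H carries charge
# only. WALLQ is a frozen surface charge (Coulomb only). X is an uncharged,
# LJ-inactive tracer used by test fixtures.

species.O.mass = 15.9994
species.O.charge = -0.8476
species.O.sigma = 3.169
species.O.epsilon = 0.6502

species.H.mass = 1.008
species.H.charge = 0.4238
species.H.sigma = 0
species.H.epsilon = 0

species.Na+.mass = 22.98977
species.Na+.charge = 1
species.Na+.sigma = 2.583
species.Na+.epsilon = 0.4184

species.Cl-.mass = 35.453
species.Cl-.charge = -1
species.Cl-.sigma = 4.401
species.Cl-.epsilon = 0.4184

species.WALLQ.mass = 0
species.WALLQ.charge = -1
species.WALLQ.sigma = 0
species.WALLQ.epsilon = 0

species.X.mass = 1
species.X.charge = 0
species.X.sigma = 0
species.X.epsilon = 0
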