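# Physical constants and unit conventions.
#
# Internal units: length Angstrom, energy kJ/mol, mass u (g/mol), time fs,
# charge e, angle radian. With this set the acceleration prefactor is exactly
# 1e-4 because kJ/mol and u share Avogadro's number:
#   a [A/fs^2] = 1e-4 * F [kJ/mol/A] / m [u].

# Coulomb factor e^2/(4 pi eps0) * N_A, in kJ mol^-1 A e^-2 (CODATA 2018).
.kw_coulomb <- 1389.35457644382

# Boltzmann constant, kJ mol^-1 K^-1 (CODATA 2018, exact).
.kw_kB <- 8.31446261815324e-3

# Acceleration conversion: (kJ/mol/A)/u -> A/fs^2.
.kw_acc <- 1e-4

# Standard atomic masses, u.
.kw_masses <- c(O = 15.999, H = 1.008)

# Reference monomer geometry: gas-phase equilibrium bond length (A) and
# bond angle (degrees) of the underlying electronic-structure minimum.
.kw_r_eq <- 0.9619
.kw_theta_eq_deg <- 105.05

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
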