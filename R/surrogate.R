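#' Parameters of the analytic labelling surrogate
#'
#' The surrogate stands in for an electronic-structure + atomic-partitioning
#' labelling pipeline: an analytic intramolecular potential energy surface
#' (PES) whose minimum sits at the monomer equilibrium geometry
#' (r = 0.9619 A, theta = 105.05 deg), a smooth per-atom partition of that
#' energy, geometry-dependent per-atom multipole moments, and synthetic
#' per-atom integration-error values L(Omega).
#'
#' The PES is
#' \deqn{E = D[1-e^{-a\Delta r_1}]^2 + D[1-e^{-a\Delta r_2}]^2 +
#'   \tfrac{1}{2}k_\theta\Delta\theta^2 + k_{rr}\Delta r_1\Delta r_2 +
#'   k_{r\theta}(\Delta r_1+\Delta r_2)\Delta\theta}
#' with displacements taken from the equilibrium values. The default force
#' constants give water-like vibrational frequencies with the bend mode well
#' below the two stretches and the asymmetric stretch above the symmetric
#' one (k_rr < 0).
#'
#' Charges are q_O = -2*qbar + delta_O, q_H = qbar + delta_H with qbar a
#' smooth function of the features near 0.55 e and delta zero-mean Gaussian
#' noise; the default `charge_noise_sd` makes about 5\% of configurations
#' exceed the 0.001 e net-charge filter. Dipoles and quadrupoles are smooth
#' local-frame functions of the features, zero in all components odd in the
#' out-of-plane axis (the monomer is planar), with hydrogen-exchange
#' covariance. L(Omega) is log-normal; the defaults put roughly 10\% of
#' configurations above the tighter 0.00005 Ha filter threshold.
#'
#' @param morse_D Morse well depth, kJ/mol.
#' @param morse_a Morse width, 1/Angstrom.
#' @param k_theta harmonic bend constant, kJ/mol/rad^2.
#' @param k_rr bond-bond coupling, kJ/mol/Angstrom^2.
#' @param k_rtheta bond-angle coupling, kJ/mol/Angstrom/rad.
#' @param r_eq,theta_eq equilibrium bond length (A) and angle (rad).
#' @param q0 mean hydrogen charge at equilibrium, e.
#' @param charge_noise_sd per-atom charge noise, e.
#' @param moment_noise_sd per-component dipole/quadrupole noise (e A^l).
#' @param lom_meanlog,lom_sdlog log-normal parameters of L(Omega), Ha.
#' @return A list of class `surrogate_params`.
#' @export
surrogate_params <- function(morse_D = 494, morse_a = 2.28,
                             k_theta = 420, k_rr = -100, k_rtheta = 70,
                             r_eq = 0.9619, theta_eq = .deg2rad(105.05),
                             q0 = 0.55, charge_noise_sd = 2.9457e-4,
                             moment_noise_sd = 1e-4,
                             lom_meanlog = -11.358, lom_sdlog = 0.8) {
  p <- list(morse_D = morse_D, morse_a = morse_a, k_theta = k_theta,
            k_rr = k_rr, k_rtheta = k_rtheta, r_eq = r_eq,
            theta_eq = theta_eq, q0 = q0,
            charge_noise_sd = charge_noise_sd,
            moment_noise_sd = moment_noise_sd,
            lom_meanlog = lom_meanlog, lom_sdlog = lom_sdlog)
  stopifnot(p$morse_D > 0, p$morse_a > 0, p$k_theta > 0,
            p$charge_noise_sd >= 0, p$moment_noise_sd >= 0)
  class(p) <- "surrogate_params"
  p
}

# Vectorised PES over internal coordinates (r1, r2 in A, th in rad).
.surrogate_energy_internal <- function(r1, r2, th, params) {
  dr1 <- r1 - params$r_eq
  dr2 <- r2 - params$r_eq
  dth <- th - params$theta_eq
  m1 <- params$morse_D * (1 - exp(-params$morse_a * dr1))^2
  m2 <- params$morse_D * (1 - exp(-params$morse_a * dr2))^2
  m1 + m2 + 0.5 * params$k_theta * dth^2 + params$k_rr * dr1 * dr2 +
    params$k_rtheta * (dr1 + dr2) * dth
}

#' Surrogate molecular energy
#'
#' Analytic intramolecular PES, zero at the equilibrium geometry.
#'
#' @param config a `water_config` (or 3 x 3 position matrix).
#' @param params a [surrogate_params()] object.
#' @return Energy in kJ/mol.
#' @export
surrogate_molecular_energy <- function(config, params = surrogate_params()) {
  f <- compute_features(config)
  unname(.surrogate_energy_internal(f[1], f[2], f[3], params))
}

# Per-atom energy shares in internal coordinates; returns cbind(E_O, E_H1, E_H2).
# O takes the bend plus half of each Morse and coupling term; each H takes
# half its own Morse term, a quarter of the bond-bond coupling and half of
# its own bond-angle coupling, so the shares are smooth, sum exactly to the
# molecular energy and swap under H1 <-> H2 exchange.
.surrogate_partition_internal <- function(r1, r2, th, params) {
  dr1 <- r1 - params$r_eq
  dr2 <- r2 - params$r_eq
  dth <- th - params$theta_eq
  m1 <- params$morse_D * (1 - exp(-params$morse_a * dr1))^2
  m2 <- params$morse_D * (1 - exp(-params$morse_a * dr2))^2
  bend <- 0.5 * params$k_theta * dth^2
  crr <- params$k_rr * dr1 * dr2
  e_o  <- bend + 0.5 * (m1 + m2) + 0.5 * crr +
    0.5 * params$k_rtheta * (dr1 + dr2) * dth
  e_h1 <- 0.5 * m1 + 0.25 * crr + 0.5 * params$k_rtheta * dr1 * dth
  e_h2 <- 0.5 * m2 + 0.25 * crr + 0.5 * params$k_rtheta * dr2 * dth
  cbind(E_O = e_o, E_H1 = e_h1, E_H2 = e_h2)
}

#' Partition the surrogate energy into atomic contributions
#'
#' A smooth per-atom split that sums exactly to
#' [surrogate_molecular_energy()] and respects hydrogen-exchange symmetry.
#' Any smooth partition with these properties exercises the atomic-energy
#' machinery; no claim is made that it equals a quantum-topological
#' partition.
#'
#' @inheritParams surrogate_molecular_energy
#' @return Named numeric length-3 vector (E_O, E_H1, E_H2), kJ/mol.
#' @export
partition_atomic_energies <- function(config, params = surrogate_params()) {
  f <- compute_features(config)
  drop(.surrogate_partition_internal(f[1], f[2], f[3], params))
}

# Noiseless local-frame moment components as functions of features.
# Returns a list of three 9-column matrices (O, H1, H2); component order
# q, Q10, Q11c, Q11s, Q20, Q21c, Q21s, Q22c, Q22s. Planarity zeroes every
# component odd in the local z axis (Q10 = mu_z, Q21c, Q21s).
.surrogate_moments_internal <- function(r1, r2, th, params) {
  dr1 <- r1 - params$r_eq
  dr2 <- r2 - params$r_eq
  dth <- th - params$theta_eq
  z <- rep(0, length(dr1))
  qbar <- params$q0 - 0.10 * (dr1 + dr2) / 2 - 0.05 * dth
  o <- cbind(q    = -2 * qbar,
             Q10  = z,
             Q11c = 0.30 + 0.15 * (dr1 + dr2) + 0.10 * dth,
             Q11s = 0.12 * (dr1 - dr2),
             Q20  = 0.15 + 0.10 * (dr1 + dr2) + 0.05 * dth,
             Q21c = z, Q21s = z,
             Q22c = -0.12 + 0.06 * (dr1 + dr2),
             Q22s = 0.08 * (dr1 - dr2))
  hmom <- function(dro, drx) {
    cbind(q    = qbar,
          Q10  = z,
          Q11c = 0.12 + 0.08 * dro + 0.04 * dth + 0.02 * drx,
          Q11s = 0.03 * (dro - drx),
          Q20  = 0.04 + 0.03 * dro,
          Q21c = z, Q21s = z,
          Q22c = 0.02 + 0.01 * dro,
          Q22s = 0.02 * (dro - drx))
  }
  list(O = o, H1 = hmom(dr1, dr2), H2 = hmom(dr2, dr1))
}

#' Label a configuration with the surrogate oracle
#'
#' Produces per-atom energies, local-frame multipole moments and synthetic
#' integration errors for one configuration. Energies are noiseless; charge
#' noise is injected so the net molecular charge departs from zero by a
#' zero-mean Gaussian amount, and L(Omega) values are drawn log-normal.
#'
#' Noise draws come from the current R RNG stream; seed upstream (or use
#' [label_ensemble()]) for reproducibility.
#'
#' @inheritParams surrogate_molecular_energy
#' @return A `labelled_config`: list with `config`, `energies` (kJ/mol),
#'   `moments` (list of three local-frame [multipole_set()]s),
#'   `integration_errors` (Ha) and `net_charge` (e).
#' @export
surrogate_label <- function(config, params = surrogate_params()) {
  f <- compute_features(config)
  en <- drop(.surrogate_partition_internal(f[1], f[2], f[3], params))
  mom <- .surrogate_moments_internal(f[1], f[2], f[3], params)
  dq <- stats::rnorm(3, 0, params$charge_noise_sd)
  dm <- if (params$moment_noise_sd > 0)
    matrix(stats::rnorm(24, 0, params$moment_noise_sd), 3, 8) else
    matrix(0, 3, 8)
  moments <- vector("list", 3L)
  for (a in 1:3) {
    row <- mom[[a]][1, ]
    moments[[a]] <- multipole_set(row[1] + dq[a],
                                  row[2:4] + dm[a, 1:3],
                                  row[5:9] + dm[a, 4:8],
                                  frame = "local")
  }
  lom <- stats::rlnorm(3, params$lom_meanlog, params$lom_sdlog)
  structure(list(config = config,
                 energies = en,
                 moments = moments,
                 integration_errors = lom,
                 net_charge = sum(dq)),
            class = "labelled_config")
}

#' Label an ensemble of configurations
#'
#' @param configs list of `water_config` objects.
#' @param params a [surrogate_params()] object.
#' @param seed integer RNG seed for the injected noise.
#' @return A `labelled_ensemble`: list of `labelled_config` objects with the
#'   parameters and seed attached as attributes.
#' @export
label_ensemble <- function(configs, params = surrogate_params(), seed = 1L) {
  set.seed(seed)
  out <- lapply(configs, surrogate_label, params = params)
  structure(out, class = "labelled_ensemble", params = params, seed = seed)
}

#' @export
print.labelled_ensemble <- function(x, ...) {
  cat(sprintf("labelled_ensemble: %d configurations (surrogate-labelled)\n",
              length(x)))
  invisible(x)
}

#' Flatten a labelled ensemble to a table
#'
#' One row per configuration: features, the three atomic energies, the
#' 3 x 9 local-frame moment components, the three L(Omega) values and the
#' net molecular charge.
#'
#' @param ensemble a `labelled_ensemble` (or list of `labelled_config`).
#' @return A `data.frame` with documented columns.
#' @export
as_label_table <- function(ensemble) {
  comp <- c("q", "Q10", "Q11c", "Q11s", "Q20", "Q21c", "Q21s", "Q22c", "Q22s")
  atoms <- c("O", "H1", "H2")
  rows <- lapply(ensemble, function(lc) {
    f <- compute_features(lc$config)
    mom <- unlist(lapply(lc$moments, function(m)
      c(m$charge, m$dipole, m$quadrupole)))
    names(mom) <- as.vector(t(outer(atoms, comp, paste, sep = ".")))
    c(r1 = unname(f[1]), r2 = unname(f[2]), theta = unname(f[3]),
      E_O = unname(lc$energies[1]), E_H1 = unname(lc$energies[2]),
      E_H2 = unname(lc$energies[3]), mom,
      LOm_O = lc$integration_errors[1], LOm_H1 = lc$integration_errors[2],
      LOm_H2 = lc$integration_errors[3], net_charge = lc$net_charge)
  })
  as.data.frame(do.call(rbind, rows))
}
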