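#' Lennard-Jones parameters for water
#'
#' Homonuclear parameters with Lorentz-Berthelot combination for O-H:
#' \eqn{\epsilon_{OH} = \sqrt{\epsilon_{OO}\epsilon_{HH}}},
#' \eqn{\sigma_{OH} = (\sigma_{OO}+\sigma_{HH})/2}. Defaults are the
#' lightly tuned cluster-stable values: eps_OO = 0.753, eps_HH = 0.015
#' kJ/mol, sig_OO = 3.23, sig_HH = 1.10 Angstrom.
#'
#' @param eps_OO,eps_HH well depths, kJ/mol.
#' @param sig_OO,sig_HH diameters, Angstrom.
#' @return An `lj_params` object with the combined `OH` terms included.
#' @export
lj_params <- function(eps_OO = 0.753, eps_HH = 0.015,
                      sig_OO = 3.23, sig_HH = 1.10) {
  stopifnot(eps_OO >= 0, eps_HH >= 0, sig_OO > 0, sig_HH > 0)
  structure(list(eps = c(OO = eps_OO, OH = sqrt(eps_OO * eps_HH), HH = eps_HH),
                 sig = c(OO = sig_OO, OH = (sig_OO + sig_HH) / 2,
                         HH = sig_HH)),
            class = "lj_params")
}

#' Shifted Lennard-Jones pair energy and radial force
#'
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - V_{LJ}(r_c)} for
#' \eqn{r \le r_c}, zero beyond, so the energy is exactly zero at the cutoff.
#' The force is the derivative of the unshifted potential (the shift is
#' constant), zero beyond the cutoff.
#'
#' @param r separation(s), Angstrom.
#' @param pair `"OO"`, `"OH"` or `"HH"`.
#' @param params an [lj_params()] object.
#' @param cutoff cutoff radius, Angstrom (default 10).
#' @return List with `energy` (kJ/mol) and `force` (radial, kJ/mol/A;
#'   positive = repulsive), vectorised over `r`.
#' @export
lj_energy_force <- function(r, pair = c("OO", "OH", "HH"),
                            params = lj_params(), cutoff = 10) {
  pair <- match.arg(pair)
  stopifnot(all(r > 0))
  eps <- params$eps[[pair]]; sig <- params$sig[[pair]]
  s6c <- (sig / cutoff)^6
  shift <- 4 * eps * (s6c^2 - s6c)
  s6 <- (sig / r)^6
  inside <- r <= cutoff
  e <- ifelse(inside, 4 * eps * (s6^2 - s6) - shift, 0)
  f <- ifelse(inside, 24 * eps * (2 * s6^2 - s6) / r, 0)
  list(energy = e, force = f)
}

# Vectorised LJ over all intermolecular pairs of a cluster.
.lj_cluster <- function(pos, mol, species, params, cutoff) {
  natoms <- nrow(pos)
  ij <- which(upper.tri(matrix(0, natoms, natoms)), arr.ind = TRUE)
  a <- ij[, 1]; b <- ij[, 2]
  keep <- mol[a] != mol[b]
  a <- a[keep]; b <- b[keep]
  Rv <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
  r2 <- rowSums(Rv^2)
  keep <- r2 <= cutoff^2
  a <- a[keep]; b <- b[keep]; Rv <- Rv[keep, , drop = FALSE]; r2 <- r2[keep]
  forces <- matrix(0, natoms, 3)
  if (!length(a)) return(list(energy = 0, forces = forces))
  r <- sqrt(r2)
  pr <- paste0(species[a], species[b])
  pr[pr == "HO"] <- "OH"
  eps <- params$eps[pr]; sig <- params$sig[pr]
  s6c <- (sig / cutoff)^6
  s6 <- (sig / r)^6
  e <- 4 * eps * (s6^2 - s6) - 4 * eps * (s6c^2 - s6c)
  fr <- 24 * eps * (2 * s6^2 - s6) / r2   # (radial force)/r
  fv <- fr * Rv                            # force on b along +Rv if repulsive
  S <- rowsum(fv, a, reorder = FALSE)
  rows <- as.integer(rownames(S)); forces[rows, ] <- forces[rows, ] - S
  S <- rowsum(fv, b, reorder = FALSE)
  rows <- as.integer(rownames(S)); forces[rows, ] <- forces[rows, ] + S
  list(energy = sum(e), forces = forces)
}

#' Intramolecular energy and forces of one molecule from kriged models
#'
#' Energy is the sum of the three atomic-energy predictions; forces are the
#' negative analytic gradients (requires p = 2 models).
#'
#' @param config a `water_config` or 3 x 3 position matrix.
#' @param energy_models list of three fitted [krig()] models (O, H1, H2), or
#'   a `water_model`.
#' @return List with `energy` (kJ/mol) and `forces` (3 x 3, kJ/mol/A).
#' @export
intramolecular_energy_forces <- function(config, energy_models) {
  if (inherits(energy_models, "water_model"))
    energy_models <- energy_models$energy
  if (length(energy_models) != 3L || !all(vapply(energy_models, inherits,
                                                 NA, "krig")))
    stop("three fitted atomic-energy models are required")
  f <- rbind(unname(compute_features(config)))
  e <- sum(vapply(energy_models, function(m) predict(m, f), 0))
  g <- Reduce(`+`, lapply(energy_models, predict_gradient, config = config))
  list(energy = e, forces = -g)
}

# Vectorised feature Jacobians: list(B1, B2, B3), each nmol x 9, the gradient
# of feature h with respect to the molecule's nine coordinates.
.feature_jacobian_batch <- function(coords) {
  d1 <- coords[, 4:6, drop = FALSE] - coords[, 1:3, drop = FALSE]
  d2 <- coords[, 7:9, drop = FALSE] - coords[, 1:3, drop = FALSE]
  r1 <- sqrt(rowSums(d1^2)); r2 <- sqrt(rowSums(d2^2))
  u1 <- d1 / r1; u2 <- d2 / r2
  cth <- rowSums(u1 * u2)
  sth <- sqrt(pmax(1 - cth^2, 1e-30))
  B1 <- cbind(-u1, u1, matrix(0, nrow(coords), 3))
  B2 <- cbind(-u2, matrix(0, nrow(coords), 3), u2)
  dH1 <- (cth * u1 - u2) / (r1 * sth)
  dH2 <- (cth * u2 - u1) / (r2 * sth)
  B3 <- cbind(-(dH1 + dH2), dH1, dH2)
  list(B1, B2, B3)
}

# Full force-field evaluation for a cluster.
#
# state: list with positions (natoms x 3), molecule, species.
# model: water_model with moment models (p = 2 throughout).
# frozen_moments: natoms x 9 local spherical components; when supplied the
# moment models are not consulted and the feature-polarization force terms
# vanish (the frame-rotation terms remain: fixed local moments still rotate
# with the molecule).
.cluster_forces <- function(state, model, L, lj = lj_params(),
                            cutoff_lj = 10, cutoff_elec = 30,
                            frozen_moments = NULL, skip_intra = FALSE) {
  pos <- state$positions
  natoms <- nrow(pos)
  nmol <- natoms / 3L
  if (is.null(state$molecule)) state$molecule <- rep(seq_len(nmol), each = 3)
  if (is.null(state$species)) state$species <- rep(c("O", "H", "H"), nmol)
  coords <- matrix(as.numeric(t(pos)), ncol = 9, byrow = TRUE)
  forces <- matrix(0, natoms, 3)
  F <- .features_matrix(coords)
  B <- .feature_jacobian_batch(coords)

  # intramolecular kriged energies and forces
  e_intra <- 0
  if (!skip_intra) {
    ep <- model$energy_pack
    pr <- kw_predict_batch(ep$F, F, ep$theta, ep$p, ep$mu, ep$W, TRUE)
    e_intra <- sum(pr$values)
    dEdf <- apply(pr$gradients, c(1, 2), sum)  # nmol x 3
    if (nmol == 1L) dEdf <- rbind(as.numeric(dEdf))
    f9 <- -(dEdf[, 1] * B[[1]] + dEdf[, 2] * B[[2]] + dEdf[, 3] * B[[3]])
    forces <- forces + matrix(as.numeric(t(f9)), natoms, 3, byrow = TRUE)
  }

  # moments: predicted (with feature gradients) or frozen
  flexible_moments <- is.null(frozen_moments)
  if (flexible_moments) {
    if (is.null(model$moment_pack))
      stop("model lacks moment models; electrostatics unavailable")
    mp <- model$moment_pack
    mpred <- kw_predict_batch(mp$F, F, mp$theta, mp$p, mp$mu, mp$W, TRUE)
    sph <- matrix(0, natoms, 9)
    for (a in 1:3)
      sph[seq(a, natoms, by = 3), ] <- mpred$values[, (a - 1) * 9 + 1:9,
                                                    drop = FALSE]
  } else {
    sph <- frozen_moments
  }

  fr <- kw_frames(coords, TRUE)
  q <- sph[, 1]
  MU <- matrix(0, natoms, 3)
  TH <- matrix(0, natoms, 9)
  Rms <- vector("list", natoms)
  Thloc <- vector("list", natoms)
  muloc <- vector("list", natoms)
  for (t in seq_len(natoms)) {
    Rm <- matrix(fr$rot[, t], 3, 3)
    Rms[[t]] <- Rm
    ml <- .dip_sph_to_cart(sph[t, 2:4])
    Tl <- .quad_sph_to_cart(sph[t, 5:9])
    muloc[[t]] <- ml
    Thloc[[t]] <- Tl
    MU[t, ] <- Rm %*% ml
    TH[t, ] <- as.numeric(Rm %*% Tl %*% t(Rm))
  }

  el <- .elec_pairs(pos, state$molecule, q, MU, TH, L, cutoff_elec,
                    want_grads = TRUE)
  forces <- forces + el$forces

  # moment-dependence (polarization + orientation) force terms
  dip_perm <- c(3, 4, 2)  # spherical (Q10,Q11c,Q11s) -> cartesian (x,y,z) rows
  for (mI in seq_len(nmol)) {
    dEdX <- numeric(9)
    dEdf <- numeric(3)
    for (a in 1:3) {
      t <- 3L * (mI - 1L) + a
      gmu <- el$gmu[t, ]
      gTh <- matrix(el$gTh[t, ], 3, 3)
      V9 <- as.numeric(outer(gmu, muloc[[t]]) +
                         2 * gTh %*% Rms[[t]] %*% Thloc[[t]])
      Dm <- matrix(fr$drot[, t], 9, 9)   # column c = vec(dR/dX_c)
      dEdX <- dEdX + as.numeric(crossprod(Dm, V9))
      if (flexible_moments) {
        G <- mpred$gradients[mI, , (a - 1) * 9 + 1:9]  # 3(features) x 9(comps)
        if (is.null(dim(G))) G <- matrix(G, 3, 9)
        gmu_loc <- as.numeric(crossprod(Rms[[t]], gmu))
        gTh_loc <- crossprod(Rms[[t]], gTh) %*% Rms[[t]]
        for (h in 1:3) {
          dEdf[h] <- dEdf[h] + el$gq[t] * G[h, 1] +
            sum(gmu_loc * G[h, dip_perm]) +
            sum(gTh_loc * .quad_sph_to_cart(G[h, 5:9]))
        }
      }
    }
    f9 <- -(dEdX + dEdf[1] * B[[1]][mI, ] + dEdf[2] * B[[2]][mI, ] +
              dEdf[3] * B[[3]][mI, ])
    idx <- 3L * (mI - 1L) + 1:3
    forces[idx, ] <- forces[idx, ] + matrix(f9, 3, 3, byrow = TRUE)
  }

  ljr <- .lj_cluster(pos, state$molecule, state$species, lj, cutoff_lj)
  forces <- forces + ljr$forces
  list(E_intra = e_intra, E_elec = el$energy, E_lj = ljr$energy,
       forces = forces, local_moments = sph)
}

#' Electrostatic energy and forces of a cluster from a water model
#'
#' Predicts local-frame moments for every molecule (the polarization
#' mechanism), rotates them to the global frame and evaluates the direct-
#' space multipolar energy and its exact negative gradient, including the
#' moment-derivative terms through the local frames and the kriging feature
#' gradients. With `frozen_moments`, fixed local moments are used and the
#' feature terms vanish.
#'
#' @param state a `sim_state` (or list with `positions`, `molecule`,
#'   `species`).
#' @param model a trained `water_model` with moment models (p = 2).
#' @param L truncation rank (1, 2 or 3).
#' @param cutoff direct-space cutoff, Angstrom.
#' @param frozen_moments optional natoms x 9 matrix of local spherical
#'   components (columns q, Q10, Q11c, Q11s, Q20, Q21c, Q21s, Q22c, Q22s).
#' @return List with `energy` (kJ/mol) and `forces` (natoms x 3, kJ/mol/A).
#' @export
electrostatic_forces <- function(state, model, L, cutoff = 30,
                                 frozen_moments = NULL) {
  if (is.null(frozen_moments)) {
    pm <- unlist(model$moment_pack$p)
    if (any(pm != 2))
      stop("electrostatic forces require p = 2 moment models")
  }
  r <- .cluster_forces(state, model, L, lj = lj_params(0, 0, 1, 1),
                       cutoff_lj = 0.1, cutoff_elec = cutoff,
                       frozen_moments = frozen_moments, skip_intra = TRUE)
  list(energy = r$E_elec, forces = r$forces)
}

#' Build an initial cluster configuration
#'
#' Places `n_mol` equilibrium-geometry molecules on a jittered cubic lattice
#' (spacing 3.1 A, jitter +/- 0.15 A) with uniformly random orientations,
#' draws Maxwell-Boltzmann velocities at `temperature` and removes the net
#' linear momentum. All O-O distances are at least 2.6 A by construction.
#'
#' @param n_mol number of molecules (>= 1).
#' @param rng_seed integer seed.
#' @param temperature target temperature, K.
#' @return A `sim_state`: positions, velocities (A/fs), masses (u), species,
#'   molecule index, `n_mol`, `time` (fs).
#' @export
initialize_cluster <- function(n_mol, rng_seed = 1L, temperature = 300) {
  stopifnot(n_mol >= 1)
  set.seed(rng_seed)
  spacing <- 3.1; jitter <- 0.15
  side <- ceiling(n_mol^(1 / 3))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  grid <- as.matrix(grid[seq_len(n_mol), ]) * spacing
  grid <- sweep(grid, 2, colMeans(grid))
  grid <- grid + matrix(stats::runif(3 * n_mol, -jitter, jitter), n_mol, 3)
  # template pivoted on the O atom so every O sits on its lattice site and
  # the 2.6 A minimum O-O distance is guaranteed by the lattice spacing
  seedp <- seed_configuration()$positions
  seedp <- sweep(seedp, 2, seedp[1, ])
  pos <- matrix(0, 3 * n_mol, 3)
  for (m in seq_len(n_mol)) {
    qv <- stats::rnorm(4)
    R <- .quat_to_rot(qv / sqrt(sum(qv^2)))
    pos[3 * (m - 1) + 1:3, ] <- sweep(seedp %*% t(R), 2, grid[m, ], `+`)
  }
  oo <- pos[seq(1, 3 * n_mol, by = 3), , drop = FALSE]
  if (n_mol > 1) {
    dmin <- min(stats::dist(oo))
    if (dmin < 2.6) stop("packing failed: O-O distance below 2.6 A")
  }
  species <- rep(c("O", "H", "H"), n_mol)
  masses <- unname(.kw_masses[species])
  vel <- .maxwell_velocities(masses, temperature)
  state <- list(positions = pos, velocities = vel, masses = masses,
                species = species,
                molecule = rep(seq_len(n_mol), each = 3),
                n_mol = n_mol, time = 0)
  class(state) <- "sim_state"
  state
}

#' Hydrogen-bonded water dimer initial state
#'
#' Deterministic near-equilibrium dimer geometry: the donor molecule points
#' one O-H bond along the O-O axis at the acceptor oxygen; the acceptor
#' plane is perpendicular to the donor plane with both hydrogens pointing
#' away. With a low starting temperature the dimer stays bound, making it
#' the standard configuration for energy-conservation (NVE) checks: the
#' direct-space electrostatic cutoff then never truncates any atom pair.
#'
#' @param oo_distance O-O separation, Angstrom.
#' @param temperature Maxwell-Boltzmann starting temperature, K.
#' @param rng_seed seed for the velocities.
#' @return A `sim_state` with 2 molecules.
#' @export
water_dimer_state <- function(oo_distance = 2.95, temperature = 100,
                              rng_seed = 1L) {
  r <- .kw_r_eq
  half <- .deg2rad(.kw_theta_eq_deg) / 2
  donor <- rbind(O  = c(0, 0, 0),
                 H1 = r * c(1, 0, 0),
                 H2 = r * c(cos(2 * half), sin(2 * half), 0))
  acc <- rbind(O  = c(oo_distance, 0, 0),
               H1 = c(oo_distance, 0, 0) + r * c(cos(half), 0, sin(half)),
               H2 = c(oo_distance, 0, 0) + r * c(cos(half), 0, -sin(half)))
  pos <- rbind(donor, acc)
  species <- rep(c("O", "H", "H"), 2)
  masses <- unname(.kw_masses[species])
  set.seed(rng_seed)
  state <- list(positions = unname(pos),
                velocities = .maxwell_velocities(masses, temperature),
                masses = masses, species = species,
                molecule = rep(1:2, each = 3), n_mol = 2L, time = 0)
  class(state) <- "sim_state"
  state
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Maxwell-Boltzmann velocities (A/fs) with net momentum removed.
.maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  sd <- 0.01 * sqrt(.kw_kB * temperature / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  ptot <- colSums(v * masses)
  sweep(v, 2, ptot / sum(masses))
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: %d molecules (%d atoms), t = %.1f fs, T = %.1f K\n",
              x$n_mol, nrow(x$positions), x$time, kinetic_temperature(x)))
  invisible(x)
}

#' Kinetic energy and temperature of a state
#'
#' Temperature uses 3N - 3 degrees of freedom (net momentum is removed at
#' initialisation); rigid-molecule states carry `ndof = 6 N_mol - 3`
#' instead.
#'
#' @param state a `sim_state`.
#' @return `kinetic_energy`: kJ/mol. `kinetic_temperature`: K.
#' @export
kinetic_energy <- function(state) {
  0.5e4 * sum(state$masses * rowSums(state$velocities^2))
}

#' @rdname kinetic_energy
#' @export
kinetic_temperature <- function(state) {
  ndof <- if (!is.null(state$ndof)) state$ndof else 3 * nrow(state$positions) - 3
  2 * kinetic_energy(state) / (.kw_kB * ndof)
}

#' Andersen thermostat collision step
#'
#' Each atom independently suffers a collision with probability
#' `collision_rate * dt` and has its velocity redrawn from the
#' Maxwell-Boltzmann distribution at `temperature`.
#'
#' @param state a `sim_state`.
#' @param temperature bath temperature, K.
#' @param collision_rate per-atom collision rate, 1/fs (default 0.01 =
#'   10 per ps).
#' @param dt timestep, fs.
#' @return The updated state. Uses the current RNG stream.
#' @export
andersen_thermostat <- function(state, temperature = 300,
                                collision_rate = 0.01, dt = 1) {
  stopifnot(collision_rate >= 0)
  if (collision_rate == 0) return(state)
  n <- nrow(state$positions)
  hit <- stats::runif(n) < collision_rate * dt
  if (any(hit)) {
    sd <- 0.01 * sqrt(.kw_kB * temperature / state$masses[hit])
    state$velocities[hit, ] <- matrix(stats::rnorm(3 * sum(hit)),
                                      sum(hit), 3) * sd
  }
  state
}

#' One velocity-Verlet step
#'
#' Standard velocity Verlet: half-kick, drift, force recomputation, half-kick.
#' Forces are in kJ/mol/A; the acceleration prefactor 1e-4 converts to
#' A/fs^2.
#'
#' @param state a `sim_state` carrying current `forces` (natoms x 3); if
#'   absent they are computed first.
#' @param dt timestep, fs.
#' @param force_fn function(state) returning at least `forces` (and any
#'   energy components, which are attached to the state).
#' @return The advanced state (with updated `forces` and `energies`).
#' @export
velocity_verlet_step <- function(state, dt, force_fn) {
  if (is.null(state$forces)) {
    ff <- force_fn(state)
    state$forces <- ff$forces
    state$energies <- ff[setdiff(names(ff), c("forces", "local_moments"))]
  }
  if (any(!is.finite(state$forces)))
    stop("non-finite forces at t = ", state$time, " fs")
  acc <- .kw_acc * state$forces / state$masses
  state$velocities <- state$velocities + 0.5 * dt * acc
  state$positions <- state$positions + dt * state$velocities
  ff <- force_fn(state)
  if (any(!is.finite(ff$forces)))
    stop("non-finite forces at t = ", state$time + dt, " fs")
  state$forces <- ff$forces
  state$energies <- ff[setdiff(names(ff), c("forces", "local_moments"))]
  acc <- .kw_acc * state$forces / state$masses
  state$velocities <- state$velocities + 0.5 * dt * acc
  state$time <- state$time + dt
  state
}

# Kabsch fit: rotation (proper) aligning centred template B onto centred A.
.kabsch <- function(A, B) {
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Reset every molecule to the rigid template geometry (mass-weighted centre
# and best-fit orientation preserved); velocities corrected by the positional
# shift so the constraint forces do no spurious work.
.rigid_reset <- function(state, template, dt) {
  m3 <- .kw_masses[c("O", "H", "H")]
  tpl <- sweep(template, 2, colSums(template * m3) / sum(m3))
  for (mI in seq_len(state$n_mol)) {
    idx <- 3L * (mI - 1L) + 1:3
    P <- state$positions[idx, , drop = FALSE]
    com <- colSums(P * m3) / sum(m3)
    Pc <- sweep(P, 2, com)
    R <- .kabsch(Pc, tpl)
    newP <- sweep(tpl %*% t(R), 2, com, `+`)
    if (dt > 0)
      state$velocities[idx, ] <- state$velocities[idx, ] +
        (newP - P) / dt
    state$positions[idx, ] <- newP
  }
  state
}

#' Run a molecular-dynamics simulation of a water cluster
#'
#' NVT (Andersen thermostat) or NVE dynamics with kriged intramolecular
#' energies/forces, polarizable multipolar electrostatics truncated at rank
#' `L`, and shifted Lennard-Jones dispersion-repulsion. Nonperiodic.
#' `rigid = TRUE` freezes the internal geometry (constraint reset to the
#' equilibrium template each step) and uses fixed local-frame moments,
#' predicted once at the template geometry.
#'
#' @param model a trained `water_model` (p = 2) with moment models.
#' @param n_mol cluster size; or supply `initial_state`.
#' @param L electrostatic truncation rank, 1, 2 or 3.
#' @param n_steps number of timesteps.
#' @param dt timestep, fs (default 1).
#' @param temperature thermostat target, K; `NULL` or
#'   `collision_rate = 0` gives NVE.
#' @param collision_rate Andersen collision rate per atom, 1/fs.
#' @param rigid freeze internal geometry and moments.
#' @param rng_seed integer seed (cluster construction, velocities,
#'   thermostat).
#' @param lj,cutoff_lj,cutoff_elec interaction parameters.
#' @param sample_every store a trajectory frame every this many steps.
#' @param initial_state optional `sim_state` to continue from.
#' @param blowup_factor abort when |E_total| exceeds this multiple of
#'   (|E_total(0)| + 100 kJ/mol); the trajectory is truncated at the last
#'   good frame with a warning.
#' @return An `md_trajectory`: `frames` (list of natoms x 3 matrices),
#'   `frame_times`, `energy` (per-step data frame with E_intra, E_elec,
#'   E_lj, E_kin, E_total, temperature and `f_net`, the largest component of
#'   the summed force vector), `state` (final), `species`, `molecule`,
#'   `params`.
#' @export
run_simulation <- function(model, n_mol = 25, L = 1, n_steps = 1000, dt = 1,
                           temperature = 300, collision_rate = 0.01,
                           rigid = FALSE, rng_seed = 1L, lj = lj_params(),
                           cutoff_lj = 10, cutoff_elec = 30,
                           sample_every = 10L, initial_state = NULL,
                           blowup_factor = 100) {
  admitted_pairs(L)
  if (!rigid) {
    pall <- c(unlist(model$energy_pack$p), unlist(model$moment_pack$p))
    if (any(pall != 2))
      stop("molecular dynamics requires p = 2 in every model")
  }
  state <- if (is.null(initial_state))
    initialize_cluster(n_mol, rng_seed,
                       if (is.null(temperature)) 300 else temperature)
  else initial_state
  n_mol <- state$n_mol
  set.seed(rng_seed + 7L)
  template <- seed_configuration()$positions
  frozen <- NULL
  if (rigid) {
    state$ndof <- 6 * n_mol - 3
    state <- .rigid_reset(state, template, dt = 0)
    fseed <- rbind(unname(compute_features(template)))
    mp <- model$moment_pack
    v <- kw_predict_batch(mp$F, fseed, mp$theta, mp$p, mp$mu, mp$W,
                          FALSE)$values
    frozen <- matrix(0, 3 * n_mol, 9)
    for (a in 1:3)
      frozen[seq(a, 3 * n_mol, by = 3), ] <-
        matrix(v[1, (a - 1) * 9 + 1:9], n_mol, 9, byrow = TRUE)
  }
  thermo <- !is.null(temperature) && collision_rate > 0
  ff <- function(s) .cluster_forces(s, model, L, lj, cutoff_lj, cutoff_elec,
                                    frozen_moments = frozen,
                                    skip_intra = rigid)
  elog <- matrix(NA_real_, n_steps, 8)
  colnames(elog) <- c("time", "E_intra", "E_elec", "E_lj", "E_kin",
                      "E_total", "temperature", "f_net")
  frames <- list(); frame_times <- numeric(0)
  e0 <- NULL
  aborted <- FALSE
  for (step in seq_len(n_steps)) {
    state <- tryCatch(velocity_verlet_step(state, dt, ff),
                      error = function(e) e)
    if (inherits(state, "error")) {
      warning("simulation aborted at step ", step, ": ",
              conditionMessage(state))
      aborted <- TRUE
      elog <- elog[seq_len(step - 1L), , drop = FALSE]
      break
    }
    if (rigid) state <- .rigid_reset(state, template, dt)
    if (thermo)
      state <- andersen_thermostat(state, temperature, collision_rate, dt)
    ek <- kinetic_energy(state)
    et <- state$energies$E_intra + state$energies$E_elec +
      state$energies$E_lj + ek
    elog[step, ] <- c(state$time, state$energies$E_intra,
                      state$energies$E_elec, state$energies$E_lj, ek, et,
                      kinetic_temperature(state),
                      max(abs(colSums(state$forces))))
    if (is.null(e0)) e0 <- abs(et) + 100
    if (!is.finite(et) || abs(et) > blowup_factor * e0) {
      warning("energy blow-up at step ", step,
              "; trajectory truncated at last good frame")
      aborted <- TRUE
      elog <- elog[seq_len(step), , drop = FALSE]
      break
    }
    if (step %% sample_every == 0L) {
      frames[[length(frames) + 1L]] <- state$positions
      frame_times <- c(frame_times, state$time)
    }
  }
  structure(list(frames = frames, frame_times = frame_times,
                 energy = as.data.frame(elog), state = state,
                 species = state$species, molecule = state$molecule,
                 aborted = aborted,
                 params = list(n_mol = n_mol, L = L, dt = dt,
                               temperature = temperature,
                               collision_rate = collision_rate,
                               rigid = rigid, rng_seed = rng_seed,
                               cutoff_lj = cutoff_lj,
                               cutoff_elec = cutoff_elec)),
            class = "md_trajectory")
}

#' Simulate method for water models
#'
#' Thin wrapper around [run_simulation()] following the `simulate()` generic
#' convention: `nsim` independent trajectories differing only in seed.
#'
#' @param object a trained `water_model`.
#' @param nsim number of trajectories.
#' @param seed base RNG seed.
#' @param ... passed to [run_simulation()].
#' @return An `md_trajectory`, or a list of them when `nsim > 1`.
#' @export
simulate.water_model <- function(object, nsim = 1, seed = 1L, ...) {
  out <- lapply(seq_len(nsim), function(i)
    run_simulation(object, rng_seed = seed + i - 1L, ...))
  if (nsim == 1) out[[1]] else out
}

#' @export
print.md_trajectory <- function(x, ...) {
  n <- nrow(x$energy)
  cat(sprintf("md_trajectory: %d molecules, L = %d, %d steps of %.2g fs%s\n",
              x$params$n_mol, x$params$L, n, x$params$dt,
              if (x$aborted) " (aborted)" else ""))
  if (n > 0)
    cat(sprintf("  final E_total = %.2f kJ/mol, mean T = %.1f K\n",
                x$energy$E_total[n], mean(x$energy$temperature)))
  invisible(x)
}

#' @export
plot.md_trajectory <- function(x, ...) {
  graphics::matplot(x$energy$time,
                    x$energy[, c("E_intra", "E_elec", "E_lj", "E_kin",
                                 "E_total")],
                    type = "l", lty = 1, xlab = "time (fs)",
                    ylab = "energy (kJ/mol)", ...)
  graphics::legend("topright", c("intra", "elec", "LJ", "kinetic", "total"),
                   col = 1:5, lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory to multi-frame XYZ
#'
#' @param trajectory an `md_trajectory`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  frames <- lapply(seq_along(trajectory$frames), function(i)
    list(elements = trajectory$species, coords = trajectory$frames[[i]],
         comment = sprintf("t = %.2f fs", trajectory$frame_times[i])))
  write_xyz(frames, path)
}
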