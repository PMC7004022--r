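test_that("shifted Lennard-Jones: zero at cutoff, shift at sigma, minimum depth", {
  lj <- lj_params()
  expect_identical(lj$eps[["OH"]], sqrt(0.753 * 0.015))
  expect_identical(lj$sig[["OH"]], (3.23 + 1.10) / 2)
  r_c <- 10
  at_c <- lj_energy_force(r_c, "OO", lj, cutoff = r_c)
  expect_identical(at_c$energy, 0)
  # at r = sigma the unshifted LJ vanishes: only the shift remains
  s6c <- (3.23 / r_c)^6
  expect_equal(lj_energy_force(3.23, "OO", lj, r_c)$energy,
               -4 * 0.753 * (s6c^2 - s6c), tolerance = 1e-12)
  # minimum at 2^(1/6) sigma with depth eps (minus the shift)
  rm <- 2^(1 / 6) * 3.23
  expect_equal(lj_energy_force(rm, "OO", lj, r_c)$energy,
               -0.753 - 4 * 0.753 * (s6c^2 - s6c), tolerance = 1e-12)
  expect_lt(abs(lj_energy_force(rm, "OO", lj, r_c)$force), 1e-12)
  # beyond the cutoff everything is zero
  far <- lj_energy_force(12, "OO", lj, r_c)
  expect_identical(c(far$energy, far$force), c(0, 0))
  # force is the derivative of the unshifted potential
  h <- 1e-7
  fd <- -(lj_energy_force(5 + h, "OH", lj)$energy -
            lj_energy_force(5 - h, "OH", lj)$energy) / (2 * h)
  expect_equal(lj_energy_force(5, "OH", lj)$force, fd, tolerance = 1e-6)
})

test_that("intramolecular energy and forces from the kriged models", {
  wm <- fx_model50()
  r <- intramolecular_energy_forces(seed_configuration(), wm)
  # the surrogate minimum is the oracle: the model's energy and force there
  # are zero up to the N_trn = 50 interpolation-error scale, far below the
  # thermal force scale (tens of kJ/mol/A)
  expect_lt(abs(r$energy), 0.2)
  expect_lt(max(abs(r$forces)), 2)
  cfg <- fx_split50()$validation[[3]]$config
  r2 <- intramolecular_energy_forces(cfg, wm$energy)
  expect_lt(max(abs(colSums(r2$forces))), 1e-10)   # translation invariance
  expect_equal(r2$energy, sum(vapply(wm$energy, function(m)
    predict(m, cfg), 0)), tolerance = 1e-12)
  expect_error(intramolecular_energy_forces(cfg, wm$energy[1:2]), "three")
})

test_that("Andersen thermostat: no-op at zero rate, deterministic, equipartition", {
  st <- initialize_cluster(4, rng_seed = 111)
  expect_identical(andersen_thermostat(st, collision_rate = 0), st)
  set.seed(1); a <- andersen_thermostat(st, 300, 0.05, 1)
  set.seed(1); b <- andersen_thermostat(st, 300, 0.05, 1)
  expect_identical(a$velocities, b$velocities)

  # equipartition oracle: independent harmonic oscillators, exactly solvable
  # force field; each oscillator's energy decorrelates once per collision, so
  # a high collision rate and many oscillators keep the standard error of the
  # mean temperature well inside the 300 +/- 10 K band
  n <- 48
  osc <- list(positions = matrix(stats::rnorm(3 * n, sd = 0.02), n, 3),
              velocities = matrix(0, n, 3),
              masses = rep(c(1.008, 15.999), n / 2),
              n_mol = n, time = 0)
  class(osc) <- "sim_state"
  k <- 3000  # kJ/mol/A^2
  ff <- function(s) list(forces = -k * s$positions)
  set.seed(112)
  temps <- numeric(6000)
  for (i in seq_len(6000)) {
    osc <- velocity_verlet_step(osc, 0.25, ff)
    osc <- andersen_thermostat(osc, 300, 0.2, 0.25)
    # external springs: no momentum conservation, so all 3n dof count
    temps[i] <- 2 * kinetic_energy(osc) / (krigwater:::.kw_kB * (3 * n))
  }
  expect_gt(mean(temps[1001:6000]), 290)
  expect_lt(mean(temps[1001:6000]), 310)
})

test_that("velocity Verlet: free flight, second-order energy error, determinism", {
  st <- list(positions = matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
             velocities = matrix(c(0.01, 0, 0, 0, 0.02, 0), 2, 3,
                                 byrow = TRUE),
             masses = c(1, 1), n_mol = 2, time = 0)
  class(st) <- "sim_state"
  ff0 <- function(s) list(forces = matrix(0, 2, 3))
  s <- st
  for (i in 1:10) s <- velocity_verlet_step(s, 1, ff0)
  expect_equal(s$positions, st$positions + 10 * st$velocities,
               tolerance = 1e-12)
  expect_equal(s$velocities, st$velocities, tolerance = 1e-14)

  # harmonic oscillator: energy error scales as dt^2
  k <- 2000; m <- 1.008
  run_osc <- function(dt, nst) {
    o <- list(positions = matrix(c(0.2, 0, 0), 1, 3),
              velocities = matrix(0, 1, 3), masses = m, n_mol = 1, time = 0)
    class(o) <- "sim_state"
    ff <- function(s) list(forces = -k * s$positions)
    emax <- 0
    e0 <- 0.5 * k * 0.2^2
    for (i in seq_len(nst)) {
      o <- velocity_verlet_step(o, dt, ff)
      e <- 0.5 * k * sum(o$positions^2) + kinetic_energy(o)
      emax <- max(emax, abs(e - e0))
    }
    emax
  }
  # fixed total time, halving dt: error ratio ~ 4 (order 2 +/- 0.1)
  e1 <- run_osc(0.4, 250)
  e2 <- run_osc(0.2, 500)
  e3 <- run_osc(0.1, 1000)
  expect_gt(log2(e1 / e2), 1.9); expect_lt(log2(e1 / e2), 2.1)
  expect_gt(log2(e2 / e3), 1.9); expect_lt(log2(e2 / e3), 2.1)
  bad <- st
  bad$forces <- matrix(NaN, 2, 3)
  expect_error(velocity_verlet_step(bad, 1, ff0), "non-finite")
})

test_that("cluster initialisation: packing, momentum, determinism", {
  st1 <- initialize_cluster(1, rng_seed = 113)
  expect_equal(st1$positions[1, ], c(0, 0, 0), tolerance = 0.16)
  f <- compute_features(st1$positions)
  expect_equal(unname(f[1:2]), c(0.9619, 0.9619), tolerance = 1e-10)
  for (n_mol in c(8, 25)) {
    st <- initialize_cluster(n_mol, rng_seed = 113 + n_mol)
    oo <- st$positions[seq(1, 3 * n_mol, 3), ]
    expect_gte(min(stats::dist(oo)), 2.6)
    p <- colSums(st$velocities * st$masses)
    expect_lt(max(abs(p)), 1e-12)
  }
  a <- initialize_cluster(6, rng_seed = 7)
  b <- initialize_cluster(6, rng_seed = 7)
  expect_identical(a, b)
})

test_that("short cluster simulation: finite energies, zero net force, determinism", {
  wm <- fx_model50()
  tr <- run_simulation(wm, n_mol = 4, L = 2, n_steps = 60, dt = 1,
                       rng_seed = 114, sample_every = 20)
  expect_false(tr$aborted)
  expect_true(all(is.finite(as.matrix(tr$energy))))
  expect_lt(max(tr$energy$f_net), 1e-9)   # Newton's third law every step
  tr2 <- run_simulation(wm, n_mol = 4, L = 2, n_steps = 60, dt = 1,
                        rng_seed = 114, sample_every = 20)
  expect_identical(tr$frames, tr2$frames)
  expect_identical(tr$energy, tr2$energy)
})

test_that("rigid mode freezes internal geometry and local moments", {
  wm <- fx_model50()
  tr <- run_simulation(wm, n_mol = 4, L = 3, n_steps = 80, dt = 1,
                       rigid = TRUE, rng_seed = 115, sample_every = 10)
  f0 <- compute_features(seed_configuration())
  for (P in tr$frames) {
    F <- krigwater:::.features_matrix(matrix(as.numeric(t(P)), 4, 9,
                                             byrow = TRUE))
    expect_lt(max(abs(sweep(F, 2, f0))), 1e-9)
  }
})

test_that("energy blow-up aborts with a truncated trajectory", {
  wm <- fx_model50()
  st <- initialize_cluster(2, rng_seed = 116)
  st$velocities <- st$velocities * 100   # absurd kinetic energy
  expect_warning(
    tr <- run_simulation(wm, initial_state = st, L = 1, n_steps = 200,
                         dt = 1, temperature = NULL, collision_rate = 0,
                         rng_seed = 116, blowup_factor = 2),
    "blow-up|aborted")
  expect_true(tr$aborted)
  expect_lt(nrow(tr$energy), 200)
})

test_that("water dimer state is a bound hydrogen-bonded start", {
  st <- water_dimer_state(rng_seed = 117)
  expect_equal(sqrt(sum((st$positions[1, ] - st$positions[4, ])^2)), 2.95)
  wm <- fx_model50()
  expect_lt(electrostatic_forces(st, wm, L = 3)$energy, -20)
})
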