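kcoul <- 1389.35457644

test_that("rank rule: admitted interaction sets for L = 1, 2, 3", {
  p1 <- admitted_pairs(1)
  expect_equal(nrow(p1), 1)
  expect_equal(unlist(p1), c(l_A = 0, l_B = 0))
  p2 <- admitted_pairs(2)
  expect_setequal(paste(p2$l_A, p2$l_B), c("0 0", "0 1", "1 0"))
  p3 <- admitted_pairs(3)
  expect_setequal(paste(p3$l_A, p3$l_B),
                  c("0 0", "0 1", "1 0", "0 2", "2 0", "1 1"))
  expect_error(admitted_pairs(0), ">= 1")
})

test_that("interaction tensor: closed forms, homogeneity, exchange symmetry", {
  expect_equal(interaction_tensor(0, 1, 0, 1, c(2, 0, 0)), 0.5)
  set.seed(91)
  for (i in 1:20) {
    Rv <- stats::rnorm(3, sd = 2)
    for (lp in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 2), c(2, 0))) {
      mA <- sample(2 * lp[1] + 1, 1); mB <- sample(2 * lp[2] + 1, 1)
      t1 <- interaction_tensor(lp[1], mA, lp[2], mB, Rv)
      # homogeneity |R| -> 2|R|
      expect_equal(interaction_tensor(lp[1], mA, lp[2], mB, 2 * Rv),
                   t1 * 2^-(lp[1] + lp[2] + 1), tolerance = 1e-12)
      # exchange symmetry of the bilinear form: T_AB(R) = T_BA(-R)
      expect_equal(t1, interaction_tensor(lp[2], mB, lp[1], mA, -Rv),
                   tolerance = 1e-12)
      # parity: T(-R) = (-1)^(lA+lB) T(R)
      expect_equal(interaction_tensor(lp[1], mA, lp[2], mB, -Rv),
                   (-1)^(lp[1] + lp[2]) * t1, tolerance = 1e-12)
    }
  }
  expect_error(interaction_tensor(0, 1, 0, 1, c(0, 0, 0)), "zero")
})

test_that("charge pair reproduces Coulomb's law", {
  A <- multipole_set(1, frame = "global")
  B <- multipole_set(-1, frame = "global")
  expect_equal(pair_electrostatic_energy(A, B, c(3, 0, 0), 1),
               -kcoul / 3, tolerance = 1e-10)
  expect_error(pair_electrostatic_energy(multipole_set(1), B, c(3, 0, 0), 1),
               "global")
})

test_that("pair energy decomposes exactly into the admitted rank terms", {
  set.seed(92)
  for (i in 1:20) {
    qa <- stats::rnorm(1); qb <- stats::rnorm(1)
    da <- stats::rnorm(3, sd = 0.3); db <- stats::rnorm(3, sd = 0.3)
    Qa <- stats::rnorm(5, sd = 0.2); Qb <- stats::rnorm(5, sd = 0.2)
    Rv <- stats::rnorm(3, sd = 3)
    A <- multipole_set(qa, da, Qa, frame = "global")
    B <- multipole_set(qb, db, Qb, frame = "global")
    single <- function(lA, lB) {
      a1 <- multipole_set(if (lA == 0) qa else 0,
                          if (lA == 1) da else numeric(3),
                          if (lA == 2) Qa else numeric(5), frame = "global")
      b1 <- multipole_set(if (lB == 0) qb else 0,
                          if (lB == 1) db else numeric(3),
                          if (lB == 2) Qb else numeric(5), frame = "global")
      pair_electrostatic_energy(a1, b1, Rv, 3)
    }
    terms <- mapply(single, c(0, 0, 1, 0, 2, 1), c(0, 1, 0, 2, 0, 1))
    eL3 <- pair_electrostatic_energy(A, B, Rv, 3)
    expect_equal(eL3, sum(terms), tolerance = 1e-11)
    # rank nesting: E(L=3) - E(L=2) equals the three added classes exactly
    eL2 <- pair_electrostatic_energy(A, B, Rv, 2)
    expect_equal(eL3 - eL2, sum(terms[4:6]), tolerance = 1e-11)
    expect_equal(eL2 - pair_electrostatic_energy(A, B, Rv, 1),
                 sum(terms[2:3]), tolerance = 1e-11)
  }
})

test_that("collinear head-to-tail dipoles match the two-point-charge limit", {
  mu <- 0.25; R <- 4
  A <- multipole_set(0, dipole = c(0, mu, 0), frame = "global")  # along +x
  e_dip <- pair_electrostatic_energy(A, A, c(R, 0, 0), 3)
  expect_equal(e_dip, -2 * mu^2 * kcoul / R^3, tolerance = 1e-10)
})

test_that("point-charge arrays converge to the multipole treatment as O(d^2)", {
  qplus <- function(q) multipole_set(q, frame = "global")
  # dipole-dipole: each dipole as +/-q at separation d along x
  mu <- 0.3; R <- 5
  e_exact <- pair_electrostatic_energy(
    multipole_set(0, c(0, mu, 0), frame = "global"),
    multipole_set(0, c(0, mu, 0), frame = "global"), c(R, 0, 0), 3)
  err_d <- vapply(c(0.04, 0.02, 0.01, 0.005), function(d) {
    q <- mu / d
    # charges at x = +/- d/2 around each center, evaluated with the L=1 code
    xs1 <- c(d / 2, -d / 2); qs1 <- c(q, -q)
    e <- 0
    for (i in 1:2) for (j in 1:2)
      e <- e + pair_electrostatic_energy(qplus(qs1[i]), qplus(qs1[j]),
                                         c(R + xs1[j] - xs1[i], 0, 0), 1)
    abs(e - e_exact)
  }, 0)
  slope <- coef(stats::lm(log(err_d) ~ log(c(0.04, 0.02, 0.01, 0.005))))[2]
  expect_gt(slope, 1.9); expect_lt(slope, 2.1)

  # charge-quadrupole: linear (q, -2q, q) array has Q20 = 2 q d^2
  Q20 <- 0.2; Rz <- 6
  e_exact2 <- pair_electrostatic_energy(
    qplus(1), multipole_set(0, numeric(3), c(Q20, 0, 0, 0, 0),
                            frame = "global"), c(0, 0, Rz), 3)
  err_d2 <- vapply(c(0.04, 0.02, 0.01, 0.005), function(d) {
    q <- Q20 / (2 * d^2)
    zs <- c(d, 0, -d); qs <- c(q, -2 * q, q)
    e <- 0
    for (j in 1:3)
      e <- e + pair_electrostatic_energy(qplus(1), qplus(qs[j]),
                                         c(0, 0, Rz + zs[j]), 1)
    abs(e - e_exact2)
  }, 0)
  slope2 <- coef(stats::lm(log(err_d2) ~ log(c(0.04, 0.02, 0.01, 0.005))))[2]
  expect_gt(slope2, 1.9); expect_lt(slope2, 2.1)
})

test_that("total cluster energy: single molecule zero, pair decomposition, rotation invariance", {
  wm <- fx_model50()
  st1 <- initialize_cluster(1, rng_seed = 93)
  mom1 <- predict(wm, list(water_config(st1$positions)), type = "moments")[[1]]
  glob1 <- lapply(1:3, function(a)
    rotate_multipoles(mom1[[a]], build_local_frame(st1$positions, a)))
  expect_equal(total_electrostatic_energy(st1$positions, glob1, L = 3), 0)

  st <- initialize_cluster(2, rng_seed = 94)
  coords <- matrix(as.numeric(t(st$positions)), 2, 9, byrow = TRUE)
  moms <- list()
  for (m in 1:2) {
    P <- st$positions[3 * (m - 1) + 1:3, ]
    loc <- predict(wm, list(water_config(P)), type = "moments")[[1]]
    for (a in 1:3)
      moms[[3 * (m - 1) + a]] <- rotate_multipoles(loc[[a]],
                                                   build_local_frame(P, a))
  }
  etot <- total_electrostatic_energy(st$positions, moms, L = 3)
  # equals the direct sum over the 9 intermolecular atom pairs
  e9 <- 0
  for (i in 1:3) for (j in 4:6)
    e9 <- e9 + pair_electrostatic_energy(moms[[i]], moms[[j]],
                                         st$positions[j, ] - st$positions[i, ],
                                         L = 3)
  expect_equal(etot, e9, tolerance = 1e-12)

  # rigid rotation of the whole cluster (positions and co-rotated moments)
  ee <- function(pos) {
    s <- list(positions = pos, molecule = st$molecule, species = st$species)
    electrostatic_forces(s, wm, L = 3)$energy
  }
  set.seed(95)
  for (i in 1:5) {
    R <- fx_rotation()
    expect_lt(abs(ee(st$positions %*% t(R)) - ee(st$positions)), 1e-10)
  }
})

test_that("electrostatic forces match finite differences including polarization", {
  wm <- fx_model50()
  st <- initialize_cluster(3, rng_seed = 96)
  ef <- electrostatic_forces(st, wm, L = 3)
  ee <- function(pos) {
    s <- st; s$positions <- pos
    electrostatic_forces(s, wm, L = 3)$energy
  }
  gfd <- fx_fd_gradient(ee, st$positions, h = 5e-5)
  expect_lt(max(abs(ef$forces + gfd)) / max(abs(gfd)), 1e-5)
  # net force and torque vanish (isolated system)
  expect_lt(max(abs(colSums(ef$forces))), 1e-9)
  tq <- colSums(t(vapply(seq_len(nrow(st$positions)), function(t)
    krigwater:::.cross3(st$positions[t, ], ef$forces[t, ]), numeric(3))))
  expect_lt(max(abs(tq)), 1e-9)
})

test_that("frozen moments reduce forces to the fixed-multipole expression", {
  wm <- fx_model50()
  st <- initialize_cluster(2, rng_seed = 97)
  full <- krigwater:::.cluster_forces(st, wm, L = 3, skip_intra = TRUE,
                                      lj = lj_params(0, 0, 1, 1),
                                      cutoff_lj = 0.1)
  frozen <- electrostatic_forces(st, wm, L = 3,
                                 frozen_moments = full$local_moments)
  expect_equal(frozen$energy, full$E_elec, tolerance = 1e-12)
  # frozen-moment forces are the FD gradient with moments held fixed
  eef <- function(pos) {
    s <- st; s$positions <- pos
    electrostatic_forces(s, wm, L = 3,
                         frozen_moments = full$local_moments)$energy
  }
  gfd <- fx_fd_gradient(eef, st$positions)
  expect_lt(max(abs(frozen$forces + gfd)) / max(abs(gfd)), 1e-6)
  # and differ from the flexible forces by the polarization terms
  expect_gt(max(abs(frozen$forces - full$forces)), 1e-6)
})
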