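test_that("normal modes: three positive eigenvalues in bend/stretch order", {
  nm <- compute_normal_modes(seed_configuration())
  expect_length(nm$eigenvalues, 3)
  expect_true(all(nm$eigenvalues > 0))
  expect_true(all(diff(nm$eigenvalues) > 0))
  # classify modes by their feature-space action: the softest is the bend,
  # then the symmetric stretch, then the asymmetric stretch
  B <- feature_jacobian(seed_configuration())
  act <- abs(B %*% nm$directions)  # 3 features x 3 modes
  expect_gt(act[3, 1] / max(act[1:2, 1]), 3)          # mode 1: mostly angle
  s2 <- act[1:2, 2]; s3 <- act[1:2, 3]
  expect_gt(min(s2) / max(act[3, 2], 1e-12), 0.5)     # stretches move bonds
  d2 <- B[1:2, ] %*% nm$directions[, 2]
  d3 <- B[1:2, ] %*% nm$directions[, 3]
  expect_gt(abs(sum(sign(d2))), 1.5)   # symmetric: both bonds same sign
  expect_lt(abs(sum(sign(d3))), 0.5)   # asymmetric: opposite signs
})

test_that("doubling the force constants doubles the eigenvalues", {
  p1 <- surrogate_params()
  p2 <- surrogate_params(morse_D = 2 * p1$morse_D, k_theta = 2 * p1$k_theta,
                         k_rr = 2 * p1$k_rr, k_rtheta = 2 * p1$k_rtheta)
  nm1 <- compute_normal_modes(seed_configuration(), params = p1)
  nm2 <- compute_normal_modes(seed_configuration(), params = p2)
  expect_equal(nm2$eigenvalues, 2 * nm1$eigenvalues, tolerance = 1e-5)
})

test_that("a non-stationary seed is rejected", {
  off <- seed_configuration()$positions
  off[2, 1] <- off[2, 1] + 0.05
  expect_error(compute_normal_modes(water_config(off)), "stationary")
})

test_that("sampling respects the 20% distortion constraint", {
  cfg <- seed_configuration()
  cs <- sample_configurations(cfg, 1000, rng_seed = 71)
  F <- t(vapply(cs, compute_features, numeric(3)))
  expect_true(all(F[, 1:2] >= 0.9619 * 0.8 - 1e-12))
  expect_true(all(F[, 1:2] <= 0.9619 * 1.2 + 1e-12))
  th0 <- 105.05 * pi / 180
  expect_true(all(F[, 3] >= 0.8 * th0 - 1e-12))
  expect_true(all(F[, 3] <= 1.2 * th0 + 1e-12))
  # the constraint is active: sampling reaches near the box edges
  expect_gt(max(F[, 1]), 0.9619 * 1.15)
  expect_lt(min(F[, 1]), 0.9619 * 0.85)
})

test_that("zero distortion returns seed copies; sampling is deterministic", {
  cfg <- seed_configuration()
  cs0 <- sample_configurations(cfg, 5, max_distortion = 0, rng_seed = 72)
  for (c0 in cs0) expect_equal(c0$positions, cfg$positions, tolerance = 1e-12)
  a <- sample_configurations(cfg, 20, rng_seed = 73)
  b <- sample_configurations(cfg, 20, rng_seed = 73)
  expect_identical(lapply(a, `[[`, "positions"), lapply(b, `[[`, "positions"))
  expect_error(sample_configurations(cfg, 0), "at least 1")
  expect_error(sample_configurations(cfg, 5, max_distortion = -0.1),
               "nonnegative")
})

test_that("smaller max_distortion gives nested feature ranges", {
  cfg <- seed_configuration()
  f_small <- t(vapply(sample_configurations(cfg, 300, 0.05, rng_seed = 74),
                      compute_features, numeric(3)))
  f_large <- t(vapply(sample_configurations(cfg, 300, 0.20, rng_seed = 74),
                      compute_features, numeric(3)))
  for (h in 1:3) {
    expect_gte(min(f_small[, h]), min(f_large[, h]))
    expect_lte(max(f_small[, h]), max(f_large[, h]))
  }
})

test_that("filter removes exactly the planted violations", {
  kept <- fx_ensemble()[1:20]
  mk <- function(lc, netq = 0, lom = 1e-5) {
    dq <- (netq - lc$net_charge) / 3
    for (a in 1:3) lc$moments[[a]]$charge <- lc$moments[[a]]$charge + dq
    lc$net_charge <- netq
    lc$integration_errors <- rep(lom, 3)
    lc
  }
  lab <- kept
  lab[[2]] <- mk(lab[[2]], netq = 0.0015)            # charge violation
  lab[[5]] <- mk(lab[[5]], lom = 7e-5)               # L(Omega) violation
  lab[[9]] <- mk(lab[[9]], netq = 0.0015, lom = 7e-5)
  for (i in setdiff(1:20, c(2, 5, 9))) lab[[i]] <- mk(lab[[i]])
  out5 <- filter_ensemble(lab, filter_policy(integration_error_threshold = 5e-5))
  expect_length(out5, 17)
  # the looser threshold retains the L(Omega) = 7e-5 configuration
  out10 <- filter_ensemble(lab, filter_policy(integration_error_threshold = 1e-4))
  expect_length(out10, 18)
  # order preserved and filtering is idempotent
  expect_identical(filter_ensemble(out5,
                                   filter_policy(integration_error_threshold = 5e-5)),
                   out5)
  # boundary: values just below the thresholds are retained (> not >=)
  edge <- mk(kept[[1]], netq = 0.00099, lom = 4.99e-5)
  expect_length(filter_ensemble(list(edge),
                                filter_policy(integration_error_threshold = 5e-5)), 1)
  # missing labels are an error
  broken <- kept[[1]]; broken$integration_errors <- NULL
  expect_error(filter_ensemble(list(broken), filter_policy()), "labels")
})

test_that("train/validation split is exact, disjoint and deterministic", {
  ens <- fx_ensemble()
  for (n_trn in c(50, 75, 125)) {
    sp <- split_train_validation(ens, n_trn, rng_seed = 75)
    expect_length(sp$train, n_trn)
    expect_length(sp$validation, length(ens) - n_trn)
  }
  sp1 <- split_train_validation(seq_len(100), 40, rng_seed = 76)
  sp2 <- split_train_validation(seq_len(100), 40, rng_seed = 76)
  expect_identical(sp1, sp2)
  expect_length(intersect(unlist(sp1$train), unlist(sp1$validation)), 0)
  sp3 <- split_train_validation(seq_len(100), 99, rng_seed = 77)
  expect_length(sp3$validation, 1)
  expect_error(split_train_validation(seq_len(100), 100), "n_train")
})
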