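test_that("kernel: closed forms, symmetry and validation", {
  expect_equal(krig_kernel(c(1, 2, 3), c(1, 2, 3), theta = c(1, 1, 1)), 1)
  expect_equal(krig_kernel(c(0, 0, 0), c(1, 0, 0), theta = c(1, 5, 5),
                           p = c(2, 2, 2)), exp(-1))
  set.seed(81)
  for (i in 1:200) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    th <- stats::runif(3, 0.1, 5); p <- stats::runif(3, 0.5, 2)
    expect_equal(krig_kernel(a, b, th, p), krig_kernel(b, a, th, p),
                 tolerance = 1e-15)
    k <- krig_kernel(a, b, th, p)
    expect_true(k > 0 && k <= 1)
  }
  expect_error(krig_kernel(1:3, 1:3, theta = c(-1, 1, 1)), "positive")
  expect_error(krig_kernel(1:3, 1:3, theta = c(1, 1, 1), p = c(3, 2, 2)),
               "0, 2")
})

test_that("concentrated log-likelihood matches hand-evaluated 2x2 algebra", {
  F <- rbind(c(0, 0, 0), c(1, 0, 0))
  y <- c(1, 3)
  th <- c(0.7, 1, 1); nug <- 1e-8
  r12 <- exp(-0.7)
  R <- matrix(c(1 + nug, r12, r12, 1 + nug), 2, 2)
  Ri <- solve(R)
  mu <- sum(Ri %*% y) / sum(Ri)
  s2 <- drop(t(y - mu) %*% Ri %*% (y - mu)) / 2
  expected <- -1 * log(s2) - 0.5 * log(det(R))
  expect_equal(concentrated_log_likelihood(F, y, th, nugget = nug), expected,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to constant shifts of the response", {
  set.seed(82)
  F <- matrix(stats::runif(30), 10, 3)
  y <- stats::rnorm(10)
  th <- c(1, 2, 0.5)
  expect_equal(concentrated_log_likelihood(F, y, th),
               concentrated_log_likelihood(F, y + 17.3, th),
               tolerance = 1e-8)
})

test_that("constant response is handled by the capped-likelihood path", {
  F <- matrix(stats::runif(30), 10, 3)
  expect_equal(concentrated_log_likelihood(F, rep(2, 10), c(1, 1, 1)), 1e10)
  m <- krig(F, rep(2.5, 10), rng_seed = 1)
  expect_equal(m$mu, 2.5)
  expect_equal(m$weights, rep(0, 10))
  expect_equal(unname(predict(m, matrix(c(9, 9, 9), 1, 3))), 2.5)
})

test_that("PSO recovers the optimum of a smooth unimodal objective", {
  x0 <- c(0.3, -1.2, 2.1)
  obj <- function(x) -sum((x - x0)^2)
  r <- pso_optimize(obj, lower = rep(-5, 3), upper = rep(5, 3),
                    control = pso_control(iterations = 200, stagnation = Inf),
                    rng_seed = 5)
  expect_lt(max(abs(r$par - x0)), 1e-3)
  r2 <- pso_optimize(obj, lower = rep(-5, 3), upper = rep(5, 3),
                     control = pso_control(iterations = 200, stagnation = Inf),
                     rng_seed = 5)
  expect_identical(r, r2)  # deterministic given the seed
  expect_error(pso_optimize(function(x) NaN, -1, 1), "non-finite")
})

test_that("exponents stay fixed at 2 unless optimised", {
  sp <- fx_split50()
  F <- t(vapply(sp$train[1:20], function(l) compute_features(l$config),
                numeric(3)))
  y <- vapply(sp$train[1:20], function(l) l$energies[1], 0)
  m <- krig(F, y, optimize_p = FALSE, rng_seed = 9)
  expect_identical(m$p, c(2, 2, 2))
  mp <- krig(F, y, optimize_p = TRUE, rng_seed = 9,
             pso = pso_control(swarm_size = 10, iterations = 30))
  expect_true(all(mp$p >= 0.5 & mp$p <= 2))
})

test_that("kriging interpolates its training data (nugget-scale residuals)", {
  wm <- fx_model50()
  models <- c(wm$energy, unlist(wm$moments, recursive = FALSE))
  for (m in models) {
    res <- residuals(m)
    # Eq.-3 exactness: the residual at point j is exactly -nugget * a_j
    expect_lt(max(abs(res + m$nugget * m$weights)),
              1e-6 * max(abs(res)) + 1e-12)
    expect_lte(max(abs(res)), 10 * m$nugget * max(abs(m$weights), 1))
  }
  # absolute scale: residuals are far below the validation error scale
  expect_lt(max(abs(residuals(wm$energy[[1]]))), 0.1)
})

test_that("1-D synthetic function matches an independent GP implementation", {
  # independent plain-R Gaussian process oracle (same kernel family)
  set.seed(83)
  f1 <- seq(0, 2 * pi, length.out = 20)
  F <- cbind(f1, 0, 0)
  y <- sin(f1)
  th <- c(2, 1, 1); nug <- 1e-10
  K <- exp(-th[1] * outer(f1, f1, function(a, b) (a - b)^2)) + nug * diag(20)
  Ki <- solve(K)
  mu <- sum(Ki %*% y) / sum(Ki)
  w <- Ki %*% (y - mu)
  fs <- seq(0.3, 6, length.out = 50)
  ko <- exp(-th[1] * outer(fs, f1, function(a, b) (a - b)^2))
  oracle <- mu + drop(ko %*% w)
  fit <- krigwater:::kw_krig_fit(krigwater:::kw_absdiff(F), y, th, c(2, 2, 2),
                                 nug, nug)
  pred <- krigwater:::kw_predict_batch(F, cbind(fs, 0, 0), rbind(th),
                                       rbind(c(2, 2, 2)), fit$mu,
                                       cbind(fit$weights), FALSE)$values
  expect_equal(drop(pred), oracle, tolerance = 1e-9)
  # and the full fitted model is accurate on held-out points
  m <- krig(F, y, rng_seed = 11)
  expect_lt(sqrt(mean((predict(m, cbind(fs, 0, 0)) - sin(fs))^2)), 1e-3)
})

test_that("prediction reverts to the trend far from all training points", {
  sp <- fx_split50()
  m <- fx_model50()$energy[[1]]
  far <- matrix(c(50, 50, 50), 1, 3)
  expect_equal(unname(predict(m, far)), m$mu, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences and vanish in translation", {
  wm <- fx_model50()
  sp <- fx_split50()
  m <- wm$energy[[2]]
  for (lc in sp$validation[1:25]) {
    g <- predict_gradient(m, lc$config)
    gfd <- fx_fd_gradient(function(P) predict(m, water_config(P)),
                          lc$config$positions)
    expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
    expect_lt(max(abs(colSums(g))), 1e-10)
  }
  mc <- krig(matrix(stats::runif(60), 20, 3), rep(1.5, 20), rng_seed = 3)
  expect_equal(predict_gradient(mc, seed_configuration()),
               matrix(0, 3, 3, dimnames = list(c("O", "H1", "H2"),
                                               c("x", "y", "z"))))
  mp <- krig(matrix(stats::runif(30), 10, 3), stats::rnorm(10),
             optimize_p = TRUE, rng_seed = 4,
             pso = pso_control(swarm_size = 8, iterations = 20))
  if (any(mp$p != 2)) expect_error(predict_gradient(mp, seed_configuration()),
                                   "p = 2")
})

test_that("duplicate features with conflicting responses need a nugget", {
  F <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 2, 2))
  expect_error(krig(F, c(0, 1, 2), nugget = 0,
                    pso = pso_control(swarm_size = 4, iterations = 5)),
               "duplicate")
})

test_that("S-curves are monotone, end at 100% and have the right median", {
  set.seed(84)
  err <- abs(stats::rnorm(101))
  sc <- s_curve(err)
  expect_true(all(diff(sc$error) >= 0))
  expect_true(all(diff(sc$cum_pct) > 0))
  expect_equal(sc$cum_pct[nrow(sc)], 100)
  expect_equal(sc$error[51], unname(stats::quantile(err, 0.5, type = 1)))
  expect_equal(mae(c(0.2, 0.4)), 0.3)
  # a perfect model gives an all-zero vertical S-curve
  sc0 <- s_curve(rep(0, 10))
  expect_true(all(sc0$error == 0))
})

test_that("validation errors use summed atomic properties in the right units", {
  wm <- fx_model50()
  sp <- fx_split50()
  val <- sp$validation[1:50]
  ee <- validation_errors(wm, val, "energy")
  qe <- validation_errors(wm, val, "net_charge")
  expect_length(ee, 50)
  expect_true(all(ee >= 0) && all(qe >= 0))
  # manual recomputation for one configuration
  lc <- val[[7]]
  pred <- sum(predict(wm, list(lc$config), type = "energies"))
  ref <- sum(lc$energies)
  expect_equal(ee[7], abs(pred - ref), tolerance = 1e-10)
})
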