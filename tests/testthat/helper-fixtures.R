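# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

# A moderate labelled ensemble (raw, unfiltered).
fx_ensemble <- function() {
  if (is.null(.fx$ens)) {
    cs <- sample_configurations(seed_configuration(), 360, rng_seed = 101)
    .fx$ens <- label_ensemble(cs, seed = 102)
  }
  .fx$ens
}

# Filtered ensemble and a 50-point training split.
fx_split50 <- function() {
  if (is.null(.fx$sp)) {
    kept <- filter_ensemble(fx_ensemble())
    .fx$sp <- split_train_validation(kept, 50, rng_seed = 103)
  }
  .fx$sp
}

# Full water model (3 energy + 27 moment models), N_trn = 50, p = 2.
fx_model50 <- function() {
  if (is.null(.fx$wm)) .fx$wm <- train_water_model(fx_split50()$train,
                                                   rng_seed = 104)
  .fx$wm
}

# Random proper rotation matrix.
fx_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Central finite-difference gradient of a scalar function of an
# natoms x 3 position matrix.
fx_fd_gradient <- function(f, positions, h = 1e-5) {
  g <- matrix(0, nrow(positions), 3)
  for (a in seq_len(nrow(positions))) for (c in 1:3) {
    pp <- positions; pm <- positions
    pp[a, c] <- pp[a, c] + h
    pm[a, c] <- pm[a, c] - h
    g[a, c] <- (f(pp) - f(pm)) / (2 * h)
  }
  g
}

# Stable central-difference oracle for a p = 2 kriging model: the difference
# of the two displaced predictions is accumulated per training point
# (weights times kernel differences), which is the same central difference
# but avoids catastrophic cancellation between the large kriging weights.
fx_fd_gradient_krig <- function(mod, positions, h = 1e-5) {
  g <- matrix(0, 3, 3)
  for (a in 1:3) for (c in 1:3) {
    Pp <- positions; Pm <- positions
    Pp[a, c] <- Pp[a, c] + h
    Pm[a, c] <- Pm[a, c] - h
    fp <- compute_features(Pp); fm <- compute_features(Pm)
    dp2 <- sweep(mod$features, 2, fp)^2
    dm2 <- sweep(mod$features, 2, fm)^2
    kp <- exp(-as.numeric(dp2 %*% mod$theta))
    km <- exp(-as.numeric(dm2 %*% mod$theta))
    g[a, c] <- sum(mod$weights * (kp - km)) / (2 * h)
  }
  g
}
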