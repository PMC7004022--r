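#' Vibrational normal modes of the monomer
#'
#' Diagonalises the mass-weighted Hessian of an intramolecular energy
#' function at the seed geometry (central finite differences, step 1e-4 A,
#' standard atomic masses O 15.999 u, H 1.008 u). The six near-zero
#' rigid-body eigenvalues are discarded; the three vibrational modes are
#' returned in ascending eigenvalue order, which for water-like force
#' constants is bend, symmetric stretch, asymmetric stretch.
#'
#' @param seed a `water_config` at a minimum of `energy_fn` (finite-difference
#'   gradient norm below `grad_tol`).
#' @param energy_fn function mapping a 3 x 3 position matrix to an energy in
#'   kJ/mol; defaults to the surrogate PES with `params`.
#' @param params [surrogate_params()] used by the default `energy_fn`.
#' @param step finite-difference step, Angstrom.
#' @param grad_tol maximum admissible gradient norm at the seed, kJ/mol/A.
#' @return A `normal_modes` object: `directions` (9 x 3 Cartesian
#'   displacement matrix, unit columns), `eigenvalues` (kJ/mol/A^2/u,
#'   ascending), `amplitudes` (characteristic displacement scales, A,
#'   proportional to 1/sqrt(eigenvalue)) and `seed`.
#' @export
compute_normal_modes <- function(seed, energy_fn = NULL,
                                 params = surrogate_params(),
                                 step = 1e-4, grad_tol = 1e-6) {
  if (is.null(energy_fn))
    energy_fn <- function(P) surrogate_molecular_energy(P, params)
  x0 <- as.numeric(t(.pos(seed)))
  f <- function(x) energy_fn(matrix(x, 3, 3, byrow = TRUE))
  hg <- 1e-5
  grad <- vapply(1:9, function(i) {
    e <- replace(numeric(9), i, hg)
    (f(x0 + e) - f(x0 - e)) / (2 * hg)
  }, 0)
  if (sqrt(sum(grad^2)) > grad_tol)
    stop("seed configuration is not a stationary point of the energy function")
  H <- matrix(0, 9, 9)
  for (i in 1:9) for (j in i:9) {
    ei <- replace(numeric(9), i, step)
    ej <- replace(numeric(9), j, step)
    H[i, j] <- H[j, i] <-
      (f(x0 + ei + ej) - f(x0 + ei - ej) - f(x0 - ei + ej) + f(x0 - ei - ej)) /
      (4 * step^2)
  }
  m <- rep(c(.kw_masses["O"], .kw_masses["H"], .kw_masses["H"]), each = 3)
  Hmw <- H / sqrt(outer(m, m))
  eg <- eigen(Hmw, symmetric = TRUE)
  vals <- rev(eg$values)          # ascending
  vecs <- eg$vectors[, 9:1, drop = FALSE]
  vib <- 7:9                       # three largest of the ascending order
  lam <- vals[vib]
  scale_ref <- max(abs(vals))
  if (any(abs(vals[1:6]) > 1e-4 * scale_ref))
    warning("rigid-body eigenvalues not cleanly separated from vibrations")
  if (any(lam <= 0))
    stop("seed is not a PES minimum: non-positive vibrational eigenvalue")
  dirs <- vecs[, vib, drop = FALSE] / sqrt(m)   # back to Cartesian
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  structure(list(directions = dirs, eigenvalues = lam,
                 amplitudes = 1 / sqrt(lam), seed = seed),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("normal_modes: 3 vibrational modes, eigenvalues (kJ/mol/A^2/u):\n")
  cat(sprintf("  %.2f", x$eigenvalues), "\n")
  invisible(x)
}

#' Stochastic normal-mode sampling of monomer configurations
#'
#' Generates an ensemble by displacing the seed geometry along its
#' vibrational normal modes with uniform random mode coefficients, rejecting
#' any candidate whose bond lengths or bond angle are distorted by more than
#' `max_distortion` (relative) from the seed values. Per-mode coefficient
#' ranges are scaled (linear estimate via the Wilson B-matrix, with a 25\%
#' overshoot) so that the constraint is active and the allowed box is
#' covered.
#'
#' @param seed a `water_config`.
#' @param n number of configurations to return.
#' @param max_distortion maximum relative distortion of each bond length and
#'   of the angle (default 0.20). Zero returns `n` copies of the seed.
#' @param rng_seed integer; the ensemble is deterministic given this seed.
#' @param modes optional precomputed [compute_normal_modes()] result.
#' @param params surrogate parameters for the default mode computation.
#' @return List of `n` `water_config` objects.
#' @export
sample_configurations <- function(seed, n, max_distortion = 0.20,
                                  rng_seed = 1L, modes = NULL,
                                  params = surrogate_params()) {
  if (n < 1) stop("n must be at least 1")
  if (max_distortion < 0) stop("max_distortion must be nonnegative")
  if (is.null(modes)) modes <- compute_normal_modes(seed, params = params)
  x0 <- as.numeric(t(.pos(seed)))
  f0 <- compute_features(seed)
  B <- feature_jacobian(seed)
  rel_scale <- c(f0[1], f0[2], f0[3])
  amp <- vapply(1:3, function(k) {
    g <- max(abs(B %*% modes$directions[, k]) / rel_scale)
    if (g < 1e-12) 0 else 1.25 * max_distortion / g
  }, 0)
  set.seed(rng_seed)
  out <- vector("list", n)
  made <- 0L
  guard <- 0L
  while (made < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("rejection sampling failed to converge")
    cc <- stats::runif(3, -amp, amp)
    x <- x0 + as.numeric(modes$directions %*% cc)
    P <- matrix(x, 3, 3, byrow = TRUE)
    fe <- tryCatch(compute_features(P), error = function(e) NULL)
    if (is.null(fe)) next
    if (all(abs(fe - f0) / rel_scale <= max_distortion)) {
      made <- made + 1L
      out[[made]] <- water_config(P, molecule_id = made)
    }
  }
  out
}

#' Ensemble filtering policy
#'
#' @param charge_tolerance maximum absolute net molecular charge, e
#'   (default 0.001).
#' @param integration_error_threshold maximum per-atom L(Omega), Ha
#'   (default 0.00005; 0.0001 is the looser standard setting).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(charge_tolerance = 0.001,
                          integration_error_threshold = 5e-5) {
  stopifnot(charge_tolerance > 0, integration_error_threshold > 0)
  structure(list(charge_tolerance = charge_tolerance,
                 integration_error_threshold = integration_error_threshold),
            class = "filter_policy")
}

#' Filter a labelled ensemble on charge and integration-error quality
#'
#' A configuration is removed iff its absolute net molecular charge exceeds
#' `charge_tolerance` or any atom's L(Omega) exceeds
#' `integration_error_threshold`. Order is preserved and the operation is
#' idempotent.
#'
#' @param labelled a `labelled_ensemble` (or list of `labelled_config`).
#' @param policy a [filter_policy()].
#' @return The retained sub-ensemble, same class and attributes.
#' @export
filter_ensemble <- function(labelled, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  keep <- vapply(labelled, function(lc) {
    if (is.null(lc$moments) || is.null(lc$integration_errors))
      stop("configuration lacks charge or integration-error labels")
    netq <- sum(vapply(lc$moments, function(m) m$charge, 0))
    abs(netq) <= policy$charge_tolerance &&
      all(lc$integration_errors <= policy$integration_error_threshold)
  }, NA)
  out <- labelled[keep]
  attributes(out) <- c(attributes(out),
                       attributes(labelled)[c("params", "seed")])
  class(out) <- class(labelled)
  out
}

#' Random train/validation split
#'
#' @param configs list (ensemble) to split.
#' @param n_train exact training-set size; must be smaller than the ensemble.
#' @param rng_seed integer; the split is deterministic given this seed.
#' @return List with elements `train` and `validation` (disjoint, order of
#'   first appearance preserved within each part).
#' @export
split_train_validation <- function(configs, n_train, rng_seed = 1L) {
  n <- length(configs)
  if (n_train < 1 || n_train >= n)
    stop("n_train must be in [1, ensemble size - 1]")
  set.seed(rng_seed)
  idx <- sort(sample.int(n, n_train))
  list(train = configs[idx], validation = configs[-idx])
}
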