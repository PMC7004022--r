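#' Particle swarm optimiser settings
#'
#' Defaults: swarm of 40 particles, 300 iterations, inertia 0.72, cognitive
#' and social coefficients 1.49, with early termination after 60 iterations
#' without improvement of the global best (absolute tolerance 1e-9).
#'
#' @param swarm_size number of particles (>= 2).
#' @param iterations maximum iterations.
#' @param inertia velocity inertia weight.
#' @param cognitive,social acceleration coefficients.
#' @param stagnation stop after this many iterations without improvement;
#'   `Inf` disables early termination.
#' @return A list of class `pso_control`.
#' @export
pso_control <- function(swarm_size = 40L, iterations = 300L, inertia = 0.72,
                        cognitive = 1.49, social = 1.49, stagnation = 60L) {
  stopifnot(swarm_size >= 2L, iterations >= 1L)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 stagnation = stagnation),
            class = "pso_control")
}

#' Global-best particle swarm optimisation
#'
#' Maximises `objective` over a box. Deterministic given `rng_seed`.
#' Velocities are clamped to the box width; particles are reflected into the
#' bounds.
#'
#' @param objective function of a numeric vector returning a scalar to be
#'   maximised; non-finite values are treated as failures.
#' @param lower,upper numeric bounds (finite, equal length).
#' @param control a [pso_control()] object.
#' @param rng_seed integer seed.
#' @return List with `par` (best point), `value` (best objective),
#'   `iterations` (iterations actually run) and `evaluations`.
#' @export
pso_optimize <- function(objective, lower, upper, control = pso_control(),
                         rng_seed = 1L) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  ns <- control$swarm_size
  set.seed(rng_seed)
  X <- matrix(stats::runif(ns * d, rep(lower, each = ns),
                           rep(upper, each = ns)), ns, d)
  vmax <- (upper - lower)
  V <- matrix(stats::runif(ns * d, rep(-vmax, each = ns) / 4,
                           rep(vmax, each = ns) / 4), ns, d)
  fx <- apply(X, 1, function(x) {
    v <- objective(x); if (is.finite(v)) v else -Inf
  })
  if (all(!is.finite(fx)))
    stop("objective is non-finite at every initial particle")
  Pbest <- X; fp <- fx
  g <- which.max(fp)
  gbest <- Pbest[g, ]; fg <- fp[g]
  evals <- ns
  stag <- 0L
  it <- 0L
  while (it < control$iterations) {
    it <- it + 1L
    r1 <- matrix(stats::runif(ns * d), ns, d)
    r2 <- matrix(stats::runif(ns * d), ns, d)
    V <- control$inertia * V +
      control$cognitive * r1 * (Pbest - X) +
      control$social * r2 * sweep(X, 2, gbest, function(a, b) b - a)
    V <- pmin(pmax(V, matrix(-vmax, ns, d, byrow = TRUE)),
              matrix(vmax, ns, d, byrow = TRUE))
    X <- X + V
    # reflect at the bounds
    for (k in seq_len(d)) {
      lo <- X[, k] < lower[k]; hi <- X[, k] > upper[k]
      X[lo, k] <- 2 * lower[k] - X[lo, k]
      X[hi, k] <- 2 * upper[k] - X[hi, k]
      X[, k] <- pmin(pmax(X[, k], lower[k]), upper[k])
    }
    fx <- apply(X, 1, function(x) {
      v <- objective(x); if (is.finite(v)) v else -Inf
    })
    evals <- evals + ns
    imp <- fx > fp
    Pbest[imp, ] <- X[imp, , drop = FALSE]
    fp[imp] <- fx[imp]
    g <- which.max(fp)
    if (fp[g] > fg + 1e-9) {
      fg <- fp[g]; gbest <- Pbest[g, ]; stag <- 0L
    } else stag <- stag + 1L
    if (stag >= control$stagnation) break
  }
  list(par = gbest, value = fg, iterations = it, evaluations = evals)
}

#' Kriging correlation kernel
#'
#' \eqn{k(f_i, f_j) = \exp(-\sum_h \theta_h |f_{h,i} - f_{h,j}|^{p_h})}.
#' The absolute value makes the kernel well defined for non-even exponents.
#'
#' @param f_i,f_j numeric feature vectors of equal length.
#' @param theta positive activity parameters, one per feature.
#' @param p smoothness exponents in (0, 2].
#' @return Correlation in (0, 1]; 1 iff the features coincide.
#' @export
krig_kernel <- function(f_i, f_j, theta, p = rep(2, length(theta))) {
  stopifnot(length(f_i) == length(f_j), length(theta) == length(f_i),
            length(p) == length(f_i))
  if (any(theta <= 0)) stop("theta must be strictly positive")
  if (any(p <= 0 | p > 2)) stop("p must lie in (0, 2]")
  exp(-sum(theta * abs(f_i - f_j)^p))
}

#' Concentrated log-likelihood of a kriging model
#'
#' With R the kernel matrix plus `nugget` on the diagonal:
#' \eqn{\hat\mu = (1'R^{-1}y)/(1'R^{-1}1)},
#' \eqn{\hat\sigma^2 = (y-\hat\mu 1)'R^{-1}(y-\hat\mu 1)/N},
#' and the returned value is
#' \eqn{-(N/2)\ln\hat\sigma^2 - \tfrac12 \ln\det R}.
#' A constant response (\eqn{\hat\sigma^2 = 0}) returns the capped value
#' 1e10; a kernel matrix that cannot be factorised returns `-Inf`.
#'
#' @param features N x 3 training feature matrix.
#' @param y training responses.
#' @param theta,p kernel hyperparameters (length 3 each).
#' @param nugget diagonal regulariser.
#' @return Scalar concentrated log-likelihood.
#' @export
concentrated_log_likelihood <- function(features, y, theta, p = c(2, 2, 2),
                                        nugget = 1e-10) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 2, length(y) == nrow(features))
  if (any(theta <= 0)) stop("theta must be strictly positive")
  if (any(p <= 0 | p > 2)) stop("p must lie in (0, 2]")
  kw_cll(kw_absdiff(features), y, theta, p, nugget)
}

# Coerce configs / labelled ensembles / matrices to a feature matrix.
.as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (inherits(x, "water_config")) return(rbind(unname(compute_features(x))))
  if (is.data.frame(x)) return(unname(as.matrix(x[, c("r1", "r2", "theta")])))
  if (is.list(x) && length(x)) {
    if (inherits(x[[1]], "water_config"))
      return(.features_matrix(.configs_to_coords(x)))
    if (inherits(x[[1]], "labelled_config"))
      return(.features_matrix(.configs_to_coords(lapply(x, `[[`, "config"))))
  }
  stop("cannot interpret input as features")
}

#' Fit a kriging (Gaussian process regression) model
#'
#' Models a scalar atomic property as a constant trend plus a weighted sum of
#' kernel correlations with the training points,
#' \deqn{Y(f) = \mu + \sum_{j=1}^{N_{trn}} a_j
#'   \exp\left(-\sum_h \theta_h |f_{h,j} - f_h|^{p_h}\right),}
#' with the hyperparameters \eqn{\theta_h} (and optionally \eqn{p_h}) fitted
#' by particle swarm maximisation of the concentrated log-likelihood.
#' \eqn{\theta_h} is searched on a log10 scale in [-3, 3]; \eqn{p_h} is fixed
#' at 2 unless `optimize_p`, in which case it is searched in [0.5, 2].
#'
#' A constant response is fitted directly (trend = that constant, all weights
#' zero) without hyperparameter search.
#'
#' @param x training features: an N x 3 matrix, a list of `water_config` or
#'   `labelled_config` objects, or a data frame with columns r1, r2, theta.
#' @param y numeric response vector of length N.
#' @param optimize_p logical; optimise the exponents as well as the
#'   activities.
#' @param nugget diagonal regulariser added to the unit-diagonal correlation
#'   matrix; default 1e-8 (absolute), escalated by factors of 10 up to 1e-6
#'   if the kernel matrix cannot be factorised (a warning reports the
#'   escalation).
#' @param pso a [pso_control()] object.
#' @param rng_seed seed for the swarm.
#' @param property optional name of the modelled property.
#' @return An object of class `krig` with components `mu`, `weights`,
#'   `theta`, `p`, `nugget`, `features`, `y`, `sigma2`, `cll`.
#' @seealso [predict.krig()], [predict_gradient()]
#' @export
krig <- function(x, y, optimize_p = FALSE, nugget = NULL,
                 pso = pso_control(), rng_seed = 1L, property = "property") {
  F <- .as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(F)
  stopifnot(n >= 2, length(y) == n, all(is.finite(F)), all(is.finite(y)))
  vy <- stats::var(y)
  # the kernel matrix has unit diagonal (a correlation matrix), so the
  # nugget is an absolute jitter: it bounds the kriging weights (hence the
  # roundoff noise of predictions and analytic gradients) uniformly across
  # properties of any scale
  if (is.null(nugget)) nugget <- 1e-8
  if (vy < 1e-24) {
    model <- structure(list(property = property, mu = y[1],
                            weights = rep(0, n), theta = rep(1, 3),
                            p = rep(2, 3), nugget = nugget, features = F,
                            y = y, sigma2 = 0, cll = 1e10,
                            optimize_p = optimize_p, rng_seed = rng_seed),
                       class = "krig")
    return(model)
  }
  dup <- duplicated(F)
  if (any(dup)) {
    same <- vapply(which(dup), function(i) {
      j <- which(colSums(abs(t(F) - F[i, ])) == 0)[1]
      abs(y[i] - y[j]) < 1e-12
    }, NA)
    if (!all(same) && nugget <= 0)
      stop("duplicate training features with differing responses and zero nugget")
  }
  D <- kw_absdiff(F)
  lower <- rep(-3, 3); upper <- rep(3, 3)
  if (optimize_p) { lower <- c(lower, rep(0.5, 3)); upper <- c(upper, rep(2, 3)) }
  obj <- function(par) {
    theta <- 10^par[1:3]
    p <- if (optimize_p) par[4:6] else c(2, 2, 2)
    kw_cll(D, y, theta, p, nugget)
  }
  opt <- pso_optimize(obj, lower, upper, control = pso, rng_seed = rng_seed)
  theta <- 10^opt$par[1:3]
  p <- if (optimize_p) opt$par[4:6] else c(2, 2, 2)
  fit <- kw_krig_fit(D, y, theta, p, nugget, 1e-6)
  if (isTRUE(fit$escalated))
    warning(sprintf("nugget escalated to %g for property '%s'",
                    fit$nugget, property))
  structure(list(property = property, mu = fit$mu,
                 weights = as.numeric(fit$weights), theta = theta, p = p,
                 nugget = fit$nugget, features = F, y = y,
                 sigma2 = fit$sigma2, cll = fit$cll,
                 optimize_p = optimize_p, rng_seed = rng_seed,
                 pso = opt[c("value", "iterations", "evaluations")]),
            class = "krig")
}

#' @export
print.krig <- function(x, ...) {
  cat(sprintf("krig model '%s': N_trn = %d\n", x$property, nrow(x$features)))
  cat(sprintf("  mu = %.6g, sigma2 = %.3g, nugget = %.1g\n",
              x$mu, x$sigma2, x$nugget))
  cat(sprintf("  theta = (%.4g, %.4g, %.4g), p = (%.3g, %.3g, %.3g)\n",
              x$theta[1], x$theta[2], x$theta[3], x$p[1], x$p[2], x$p[3]))
  invisible(x)
}

#' @export
coef.krig <- function(object, ...) {
  c(mu = object$mu,
    theta1 = object$theta[1], theta2 = object$theta[2],
    theta3 = object$theta[3],
    p1 = object$p[1], p2 = object$p[2], p3 = object$p[3])
}

#' @export
residuals.krig <- function(object, ...) {
  drop(kw_predict_batch(object$features, object$features,
                        rbind(object$theta), rbind(object$p),
                        object$mu, cbind(object$weights),
                        FALSE)$values) - object$y
}

#' Predict an atomic property from a kriging model
#'
#' Exact evaluation of the kriging predictor at new feature points.
#'
#' @param object a fitted [krig()] model.
#' @param newdata features in any form accepted by [krig()].
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.krig <- function(object, newdata, ...) {
  F <- .as_feature_matrix(newdata)
  drop(kw_predict_batch(object$features, F, rbind(object$theta),
                        rbind(object$p), object$mu, cbind(object$weights),
                        FALSE)$values)
}

# Gradient of the predictor with respect to the features, q x 3.
.krig_feature_gradient <- function(object, F) {
  kw_predict_batch(object$features, F, rbind(object$theta), rbind(object$p),
                   object$mu, cbind(object$weights), TRUE)$gradients[, , 1,
                                                                     drop = TRUE]
}

#' Analytic Cartesian gradient of a kriging prediction
#'
#' Chain rule through the internal-coordinate features:
#' \eqn{\partial Y/\partial x = \sum_h (\partial Y/\partial f_h)
#' (\partial f_h/\partial x)} with the feature Jacobian from
#' [feature_jacobian()]. Requires all exponents equal to 2 (the predictor is
#' otherwise not differentiable at training points).
#'
#' @param object a fitted [krig()] model with `p = (2, 2, 2)`.
#' @param config a `water_config` or 3 x 3 position matrix.
#' @return 3 x 3 matrix of derivatives, rows O, H1, H2, columns x, y, z.
#' @export
predict_gradient <- function(object, config) {
  stopifnot(inherits(object, "krig"))
  if (any(object$p != 2))
    stop("analytic gradients require p = 2 for every feature")
  f <- rbind(unname(compute_features(config)))
  g <- .krig_feature_gradient(object, f)      # length 3
  B <- feature_jacobian(config)               # 3 x 9
  out <- matrix(as.numeric(g %*% B), 3, 3, byrow = TRUE)
  dimnames(out) <- list(c("O", "H1", "H2"), c("x", "y", "z"))
  out
}

#' Per-configuration summed-property prediction errors
#'
#' The model-quality measure behind S-curves and MAE tables: for each
#' validation configuration, the absolute difference between the predicted
#' and reference sum over atoms of either the atomic energies (kJ/mol) or the
#' atomic charges (reported in milli-electron).
#'
#' @param models list of three fitted [krig()] models (O, H1, H2) for the
#'   property, or a `water_model`.
#' @param labelled validation `labelled_ensemble`.
#' @param property `"energy"` or `"net_charge"`.
#' @return Numeric vector of absolute errors, one per configuration.
#' @export
validation_errors <- function(models, labelled,
                              property = c("energy", "net_charge")) {
  property <- match.arg(property)
  if (length(labelled) == 0) stop("validation set is empty")
  if (inherits(models, "water_model"))
    models <- if (property == "energy") models$energy else
      lapply(models$moments, `[[`, "q")
  stopifnot(length(models) == 3L)
  F <- .as_feature_matrix(labelled)
  pred <- rowSums(vapply(models, function(m) predict(m, F),
                         numeric(nrow(F))))
  if (property == "energy") {
    ref <- vapply(labelled, function(lc) sum(lc$energies), 0)
    abs(pred - ref)
  } else {
    ref <- vapply(labelled, function(lc)
      sum(vapply(lc$moments, `[[`, 0, "charge")), 0)
    1000 * abs(pred - ref)
  }
}

#' S-curve of validation errors
#'
#' Sorted absolute prediction errors against the cumulative percentage of
#' validation configurations; the standard visual summary of kriging model
#' quality (steep and left-shifted is better).
#'
#' @param errors numeric vector of absolute errors (e.g. from
#'   [validation_errors()]).
#' @return An `s_curve` data frame with columns `error` (ascending) and
#'   `cum_pct` (reaching 100).
#' @export
s_curve <- function(errors) {
  stopifnot(length(errors) > 0, all(errors >= 0))
  e <- sort(errors)
  structure(data.frame(error = e,
                       cum_pct = 100 * seq_along(e) / length(e)),
            class = c("s_curve", "data.frame"))
}

#' @export
plot.s_curve <- function(x, ..., log = "x") {
  graphics::plot(pmax(x$error, .Machine$double.xmin), x$cum_pct, type = "s",
                 log = log, xlab = "absolute prediction error",
                 ylab = "cumulative % of validation set", ...)
  invisible(x)
}

#' Mean absolute error of a validation set
#'
#' @param errors numeric vector of absolute per-configuration errors.
#' @return Scalar mean.
#' @export
mae <- function(errors) {
  stopifnot(length(errors) > 0)
  mean(abs(errors))
}
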