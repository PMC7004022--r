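.traj_fields <- function(trajectory) {
  if (inherits(trajectory, "md_trajectory"))
    return(list(frames = trajectory$frames, species = trajectory$species,
                molecule = trajectory$molecule))
  stopifnot(is.list(trajectory$frames))
  list(frames = trajectory$frames, species = trajectory$species,
       molecule = trajectory$molecule)
}

#' Radial distribution function of a cluster trajectory
#'
#' Histogram of pair distances normalised by the ideal-gas pair count at the
#' cluster's mean density. A cluster has no periodic box density, so the
#' reference is a uniform "gyration sphere": radius
#' \eqn{R_{eff} = \sqrt{5/3}\, R_g} (uniform-sphere equivalent of the radius
#' of gyration of all atoms), recomputed per frame, including the exact
#' finite-sphere pair-distance factor
#' \eqn{\gamma(r) = 1 - 3r/(4R_{eff}) + r^3/(16 R_{eff}^3)} so that an ideal
#' gas in the sphere gives g(r) = 1 at every r. Peak positions are
#' independent of this convention; peak heights are not, and the convention
#' is recorded in the result.
#'
#' @param trajectory an `md_trajectory` (or list with `frames`, `species`,
#'   `molecule`).
#' @param pair_type `"OO"`, `"OH"` or `"HH"`.
#' @param r_max histogram range, Angstrom.
#' @param bin_width bin width, Angstrom.
#' @param include_intramolecular count pairs within one molecule; default
#'   TRUE for OH and HH (where the intramolecular peak is a real feature),
#'   FALSE for OO (no intramolecular O-O pairs exist anyway).
#' @return An `rdf_result` data frame with columns `r` (bin centres) and
#'   `g`; attributes record the convention, bin width and frame count.
#' @export
rdf <- function(trajectory, pair_type = c("OO", "OH", "HH"), r_max = 10,
                bin_width = 0.05, include_intramolecular = NULL) {
  pair_type <- match.arg(pair_type)
  tf <- .traj_fields(trajectory)
  if (length(tf$frames) < 1) stop("trajectory has no frames")
  if (is.null(include_intramolecular))
    include_intramolecular <- pair_type != "OO"
  s1 <- substr(pair_type, 1, 1); s2 <- substr(pair_type, 2, 2)
  i1 <- which(tf$species == s1)
  i2 <- which(tf$species == s2)
  if (!length(i1) || !length(i2)) stop("empty atom selection")
  breaks <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(breaks) - 1L)
  ideal <- numeric(length(breaks) - 1L)
  shell_vol <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  for (P in tf$frames) {
    if (s1 == s2) {
      pr <- t(utils::combn(i1, 2))
    } else {
      pr <- as.matrix(expand.grid(a = i1, b = i2))
    }
    if (!include_intramolecular)
      pr <- pr[tf$molecule[pr[, 1]] != tf$molecule[pr[, 2]], , drop = FALSE]
    if (!nrow(pr)) next
    d <- sqrt(rowSums((P[pr[, 1], , drop = FALSE] -
                         P[pr[, 2], , drop = FALSE])^2))
    counts <- counts + graphics::hist(d[d < r_max], breaks = breaks,
                                      plot = FALSE)$counts
    cen <- colMeans(P)
    rg2 <- mean(rowSums(sweep(P, 2, cen)^2))
    reff <- sqrt(5 / 3 * rg2)
    vol <- 4 / 3 * pi * reff^3
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    geom <- pmax(1 - 3 * mids / (4 * reff) + mids^3 / (16 * reff^3), 0)
    ideal <- ideal + nrow(pr) * shell_vol / vol * geom
  }
  g <- ifelse(ideal > 0, counts / ideal, 0)
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2, g = g)
  structure(out, class = c("rdf_result", "data.frame"),
            pair_type = pair_type, bin_width = bin_width,
            frames = length(tf$frames),
            include_intramolecular = include_intramolecular,
            normalization = "uniform gyration-sphere with finite-size pair factor, per frame")
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (A)",
                 ylab = sprintf("g_%s(r)", attr(x, "pair_type")), ...)
  invisible(x)
}

#' Internal-coordinate distributions of a trajectory
#'
#' Normalised histograms (density scale: unit integral) of the O-H bond
#' lengths (both bonds pooled) and the H-O-H angle over all molecules and
#' frames, with the bin-centre mode of each. Reference values mark the
#' monomer equilibrium geometry (0.9619 A, 105.05 deg); ties in the mode are
#' broken toward smaller values.
#'
#' @param trajectory an `md_trajectory` (or compatible list).
#' @param bond_bin,angle_bin bin widths (Angstrom, degrees).
#' @return List with `bond` and `angle` histogram data frames (`mid`,
#'   `density`), `bond_mode`, `angle_mode`, and the reference values.
#' @export
internal_coordinate_distributions <- function(trajectory, bond_bin = 0.005,
                                              angle_bin = 0.5) {
  tf <- .traj_fields(trajectory)
  if (length(tf$frames) < 1) stop("trajectory has no frames")
  feats <- do.call(rbind, lapply(tf$frames, function(P) {
    nmol <- nrow(P) / 3L
    .features_matrix(matrix(as.numeric(t(P)), ncol = 9, byrow = TRUE))
  }))
  bonds <- c(feats[, 1], feats[, 2])
  angles <- .rad2deg(feats[, 3])
  histo <- function(x, w) {
    breaks <- seq(floor(min(x) / w) * w - w / 2,
                  ceiling(max(x) / w) * w + w / 2, by = w)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, density = h$density)
  }
  hb <- histo(bonds, bond_bin)
  ha <- histo(angles, angle_bin)
  list(bond = hb, angle = ha,
       bond_mode = hb$mid[which.max(hb$density)],
       angle_mode = ha$mid[which.max(ha$density)],
       bond_ref = .kw_r_eq, angle_ref = .kw_theta_eq_deg)
}

#' Bond-scan validation of a trained model
#'
#' One O-H bond is scanned (default 0.85 to 1.15 A in 0.005 A steps, 61
#' points) while the other is fixed at 0.9619 A and the angle at each value
#' in `angles_deg` (the equilibrium 105.05 deg and the 100 deg mode observed
#' in cluster simulations). At each point the molecular energy (relative to
#' the global minimum) and the oxygen charge are computed from the surrogate
#' oracle and from the kriging models.
#'
#' @param model a trained `water_model` (moment models needed for q_O).
#' @param params [surrogate_params()] of the oracle used as reference.
#' @param r_range scan range, Angstrom.
#' @param step scan step, Angstrom.
#' @param fixed_bond the other O-H bond length, Angstrom.
#' @param angles_deg angles to scan at, degrees.
#' @return Data frame with columns `r`, `theta_deg`, `E_ref`, `E_pred`,
#'   `q_O_ref`, `q_O_pred` (energies kJ/mol, charges e).
#' @export
bond_scan <- function(model, params = surrogate_params(),
                      r_range = c(0.85, 1.15), step = 0.005,
                      fixed_bond = 0.9619, angles_deg = c(105.05, 100)) {
  rs <- seq(r_range[1], r_range[2], by = step)
  out <- list()
  for (th_deg in angles_deg) {
    th <- .deg2rad(th_deg)
    configs <- lapply(rs, function(r) {
      p <- rbind(O = c(0, 0, 0),
                 H1 = c(r, 0, 0),
                 H2 = fixed_bond * c(cos(th), sin(th), 0))
      water_config(p)
    })
    F <- .features_matrix(.configs_to_coords(configs))
    e_ref <- .surrogate_energy_internal(F[, 1], F[, 2], F[, 3], params)
    e_pred <- predict(model, F, type = "energy")
    q_ref <- .surrogate_moments_internal(F[, 1], F[, 2], F[, 3],
                                         params)$O[, "q"]
    q_pred <- if (!is.null(model$moments))
      predict(model$moments$O$q, F) else rep(NA_real_, length(rs))
    out[[length(out) + 1L]] <- data.frame(r = rs, theta_deg = th_deg,
                                          E_ref = e_ref, E_pred = e_pred,
                                          q_O_ref = q_ref, q_O_pred = q_pred)
  }
  do.call(rbind, out)
}

#' Plot method: bond-scan comparison for a water model
#'
#' @param x a `water_model`.
#' @param ... passed to [bond_scan()].
#' @export
plot.water_model <- function(x, ...) {
  sc <- bond_scan(x, ...)
  sp <- split(sc, sc$theta_deg)
  graphics::plot(NULL, xlim = range(sc$r), ylim = range(sc$E_ref, sc$E_pred),
                 xlab = "r(O-H) (A)", ylab = "E (kJ/mol)")
  i <- 0
  for (s in sp) {
    i <- i + 1
    graphics::lines(s$r, s$E_ref, col = i, lty = 1)
    graphics::points(s$r, s$E_pred, col = i, pch = 1, cex = 0.5)
  }
  graphics::legend("top", legend = sprintf("theta = %s deg", names(sp)),
                   col = seq_along(sp), lty = 1, bty = "n")
  invisible(x)
}

#' Model-quality grid: MAE versus training-set size, filter and exponents
#'
#' Trains energy and charge models over the full factorial grid of
#' training-set sizes, integration-error thresholds and exponent modes
#' (fixed p = 2 versus optimised), and reports the validation MAE of the
#' summed atomic energies (kJ/mol) and of the net molecular charge
#' (milli-electron) for each cell. The default menu (6 sizes x 2 thresholds
#' x 2 p-modes) has 24 cells.
#'
#' @param labelled an unfiltered `labelled_ensemble`.
#' @param n_train vector of training-set sizes.
#' @param thresholds L(Omega) thresholds, Ha.
#' @param optimize_p logical vector of exponent modes.
#' @param n_validation validation-set size (default: all remaining).
#' @param rng_seed base seed (split and swarm seeds derive from it).
#' @param pso a [pso_control()].
#' @return Data frame with one row per cell: `n_train`, `threshold`,
#'   `optimize_p`, `mae_energy_kjmol`, `mae_charge_me`.
#' @export
mae_grid <- function(labelled, n_train = c(50, 75, 125, 250, 500, 1000),
                     thresholds = c(1e-4, 5e-5),
                     optimize_p = c(FALSE, TRUE), n_validation = NULL,
                     rng_seed = 1L, pso = pso_control()) {
  grid <- expand.grid(n_train = n_train, threshold = thresholds,
                      optimize_p = optimize_p)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    keep <- filter_ensemble(labelled,
                            filter_policy(integration_error_threshold =
                                            g$threshold))
    if (length(keep) <= g$n_train)
      stop(sprintf("ensemble too small: %d retained at threshold %g, need > %d",
                   length(keep), g$threshold, g$n_train))
    sp <- split_train_validation(keep, g$n_train, rng_seed = rng_seed + i)
    val <- if (is.null(n_validation)) sp$validation
    else sp$validation[seq_len(min(n_validation, length(sp$validation)))]
    F <- .as_feature_matrix(sp$train)
    seed0 <- (rng_seed + 31L * i) %% .Machine$integer.max
    emod <- lapply(1:3, function(a)
      krig(F, vapply(sp$train, function(lc) lc$energies[a], 0),
           optimize_p = g$optimize_p, pso = pso, rng_seed = seed0 + a))
    qmod <- lapply(1:3, function(a)
      krig(F, vapply(sp$train, function(lc) lc$moments[[a]]$charge, 0),
           optimize_p = g$optimize_p, pso = pso, rng_seed = seed0 + 3L + a))
    rows[[i]] <- data.frame(
      n_train = g$n_train, threshold = g$threshold,
      optimize_p = g$optimize_p,
      mae_energy_kjmol = mae(validation_errors(emod, val, "energy")),
      mae_charge_me = mae(validation_errors(qmod, val, "net_charge")))
  }
  do.call(rbind, rows)
}
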