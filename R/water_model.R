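.kw_comp_names <- c("q", "Q10", "Q11c", "Q11s", "Q20", "Q21c", "Q21s",
                    "Q22c", "Q22s")
.kw_atom_names <- c("O", "H1", "H2")

#' Train a complete water force-field model
#'
#' Fits independent kriging models, all sharing one training set, for every
#' atomic property of the monomer: the three atomic energies and (optionally)
#' the 3 x 9 local-frame multipole components. These models are the force
#' field: summed atomic energies give the intramolecular potential, and the
#' moment models give geometry-dependent (hence polarizable) multipolar
#' electrostatics.
#'
#' @param train a `labelled_ensemble` used as the training set (typically the
#'   `train` part of [split_train_validation()]).
#' @param optimize_p optimise the kernel exponents as well as the activities
#'   (exponents fixed at 2 otherwise). Molecular dynamics requires p = 2.
#' @param nugget,pso,rng_seed passed to [krig()]; each property model gets a
#'   distinct deterministic seed derived from `rng_seed`.
#' @param moments train the 27 multipole models too (required for
#'   electrostatics; skip for intramolecular-only studies).
#' @return An object of class `water_model` with elements `energy` (list of
#'   three [krig()] models), `moments` (list of three lists of nine models,
#'   or NULL) and `meta`.
#' @seealso [predict.water_model()], [simulate.water_model()],
#'   [write_water_model()]
#' @export
train_water_model <- function(train, optimize_p = FALSE, nugget = NULL,
                              pso = pso_control(), rng_seed = 1L,
                              moments = TRUE) {
  stopifnot(length(train) >= 2)
  F <- .as_feature_matrix(train)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    (rng_seed * 1000L + seed_i) %% .Machine$integer.max
  }
  energy <- vector("list", 3L)
  names(energy) <- .kw_atom_names
  for (a in 1:3) {
    y <- vapply(train, function(lc) lc$energies[a], 0)
    energy[[a]] <- krig(F, y, optimize_p = optimize_p, nugget = nugget,
                        pso = pso, rng_seed = next_seed(),
                        property = paste0("E_", .kw_atom_names[a]))
  }
  mom <- NULL
  if (moments) {
    mom <- vector("list", 3L)
    names(mom) <- .kw_atom_names
    for (a in 1:3) {
      mom[[a]] <- vector("list", 9L)
      names(mom[[a]]) <- .kw_comp_names
      vals <- t(vapply(train, function(lc) {
        m <- lc$moments[[a]]
        c(m$charge, m$dipole, m$quadrupole)
      }, numeric(9)))
      for (cmp in 1:9) {
        mom[[a]][[cmp]] <- krig(F, vals[, cmp], optimize_p = optimize_p,
                                nugget = nugget, pso = pso,
                                rng_seed = next_seed(),
                                property = paste(.kw_atom_names[a],
                                                 .kw_comp_names[cmp],
                                                 sep = "."))
      }
    }
  }
  obj <- structure(list(energy = energy, moments = mom,
                        meta = list(n_train = length(train),
                                    optimize_p = optimize_p,
                                    rng_seed = rng_seed,
                                    trained = format(Sys.time(), "%Y-%m-%d"))),
                   class = "water_model")
  .build_packs(obj)
}

# Stack per-model hyperparameters/weights for batched C++ prediction.
# All models trained by train_water_model share the training features.
.build_packs <- function(model) {
  pack <- function(models) {
    list(F = models[[1]]$features,
         theta = t(vapply(models, `[[`, numeric(3), "theta")),
         p = t(vapply(models, `[[`, numeric(3), "p")),
         mu = vapply(models, `[[`, 0, "mu"),
         W = vapply(models, `[[`, numeric(nrow(models[[1]]$features)),
                    "weights"))
  }
  model$energy_pack <- pack(model$energy)
  if (!is.null(model$moments)) {
    flat <- unlist(model$moments, recursive = FALSE)  # atom-major, 27 models
    model$moment_pack <- pack(flat)
  }
  model
}

#' @export
print.water_model <- function(x, ...) {
  cat(sprintf("water_model: N_trn = %d, p %s, %s\n", x$meta$n_train,
              if (x$meta$optimize_p) "optimized" else "= 2",
              if (is.null(x$moments)) "energies only"
              else "energies + rank 0-2 moments"))
  invisible(x)
}

#' @export
summary.water_model <- function(object, ...) {
  res <- vapply(object$energy, function(m) max(abs(residuals(m))), 0)
  cat(sprintf("water_model trained on %d configurations (p %s)\n",
              object$meta$n_train,
              if (object$meta$optimize_p) "optimized" else "fixed at 2"))
  cat("energy models (theta, max training residual kJ/mol):\n")
  for (m in object$energy)
    cat(sprintf("  %-5s theta = (%8.3g, %8.3g, %8.3g)  max|res| = %.2e\n",
                m$property, m$theta[1], m$theta[2], m$theta[3],
                max(abs(residuals(m)))))
  if (!is.null(object$moments))
    cat(sprintf("moment models: 27 (3 atoms x 9 components), max training residual %.2e\n",
                max(vapply(unlist(object$moments, recursive = FALSE),
                           function(m) max(abs(residuals(m))), 0))))
  invisible(res)
}

#' @export
coef.water_model <- function(object, ...) {
  mods <- c(object$energy,
            if (!is.null(object$moments))
              unlist(object$moments, recursive = FALSE))
  do.call(rbind, lapply(mods, function(m)
    data.frame(property = m$property, mu = m$mu,
               theta1 = m$theta[1], theta2 = m$theta[2], theta3 = m$theta[3],
               p1 = m$p[1], p2 = m$p[2], p3 = m$p[3], nugget = m$nugget)))
}

#' @export
residuals.water_model <- function(object, ...) {
  vapply(object$energy, residuals, numeric(length(object$energy[[1]]$y)))
}

#' Predict atomic properties for configurations
#'
#' @param object a trained `water_model`.
#' @param newdata configurations (any form accepted by [krig()]).
#' @param type `"energies"` for the per-atom energy matrix, `"energy"` for
#'   the summed molecular energy, `"moments"` for local-frame
#'   [multipole_set()]s.
#' @param ... unused.
#' @return Matrix n x 3 (`"energies"`), numeric (`"energy"`) or a list (one
#'   element per configuration) of lists of three `multipole_set`s
#'   (`"moments"`).
#' @export
predict.water_model <- function(object, newdata,
                                type = c("energies", "energy", "moments"),
                                ...) {
  type <- match.arg(type)
  F <- .as_feature_matrix(newdata)
  if (type %in% c("energies", "energy")) {
    ep <- object$energy_pack
    v <- kw_predict_batch(ep$F, F, ep$theta, ep$p, ep$mu, ep$W, FALSE)$values
    colnames(v) <- paste0("E_", .kw_atom_names)
    return(if (type == "energy") rowSums(v) else v)
  }
  if (is.null(object$moments)) stop("model was trained without moment models")
  mp <- object$moment_pack
  v <- kw_predict_batch(mp$F, F, mp$theta, mp$p, mp$mu, mp$W, FALSE)$values
  lapply(seq_len(nrow(F)), function(i) {
    lapply(1:3, function(a) {
      s <- v[i, (a - 1) * 9 + 1:9]
      multipole_set(s[1], s[2:4], s[5:9], frame = "local")
    })
  })
}

#' Serialize a water model to a versioned JSON document
#'
#' Stores every kriging model (trend, weights, hyperparameters, nugget and
#' training features) plus provenance metadata; [read_water_model()] restores
#' a fully functional model.
#'
#' @param model a `water_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_water_model <- function(model, path) {
  ser <- function(m) list(property = m$property, mu = m$mu,
                          weights = m$weights, theta = m$theta, p = m$p,
                          nugget = m$nugget, y = m$y)
  doc <- list(format = "krigwater/water_model", version = 1L,
              meta = model$meta,
              features = model$energy[[1]]$features,
              energy = lapply(model$energy, ser),
              moments = if (is.null(model$moments)) NULL else
                lapply(model$moments, function(at) lapply(at, ser)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_water_model
#' @export
read_water_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "krigwater/water_model"))
    stop("not a water_model document: ", path)
  F <- as.matrix(doc$features)
  de <- function(s) {
    m <- list(property = s$property, mu = s$mu, weights = as.numeric(s$weights),
              theta = as.numeric(s$theta), p = as.numeric(s$p),
              nugget = s$nugget, features = F, y = as.numeric(s$y),
              sigma2 = NA_real_, cll = NA_real_)
    class(m) <- "krig"
    if (length(m$weights) != nrow(F) || any(!is.finite(m$theta)))
      stop("corrupt model '", s$property, "' in ", path,
           ": weight/feature length mismatch or non-finite hyperparameters")
    m
  }
  energy <- lapply(doc$energy, de)
  moments <- if (!is.null(doc$moments))
    lapply(doc$moments, function(at) lapply(at, de)) else NULL
  obj <- structure(list(energy = energy, moments = moments, meta = doc$meta),
                   class = "water_model")
  .build_packs(obj)
}
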