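#' Pipeline run configuration
#'
#' Bundles the per-stage settings of the end-to-end workflow (sample ->
#' label -> filter -> split -> train -> validate -> simulate -> analyze)
#' with the standard study defaults: 20\% maximum distortion, 0.001 e charge
#' tolerance, 0.00005 Ha integration-error threshold, 1 fs timestep, 300 K,
#' 10 / 30 A Lennard-Jones / electrostatic cutoffs.
#'
#' @param n_samples ensemble size drawn by normal-mode sampling.
#' @param max_distortion sampling constraint (relative).
#' @param charge_tolerance,integration_error_threshold filter policy.
#' @param n_train training-set size.
#' @param optimize_p optimise kernel exponents (MD requires FALSE).
#' @param n_mol,L,n_steps,dt,temperature,collision_rate,rigid MD settings.
#' @param rng_seed base seed; each stage derives its own from it.
#' @param pso a [pso_control()].
#' @param surrogate a [surrogate_params()].
#' @return A `run_config` list.
#' @export
run_config <- function(n_samples = 2000, max_distortion = 0.20,
                       charge_tolerance = 0.001,
                       integration_error_threshold = 5e-5,
                       n_train = 50, optimize_p = FALSE,
                       n_mol = 25, L = 1, n_steps = 1000, dt = 1,
                       temperature = 300, collision_rate = 0.01,
                       rigid = FALSE, rng_seed = 1L, pso = pso_control(),
                       surrogate = surrogate_params()) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg, stage) {
  s <- jsonlite::toJSON(cfg[!vapply(cfg, is.function, NA)],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  writeLines(c(stage, s), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

#' Run the full pipeline
#'
#' Executes every stage, writing artifacts under `out_dir`; a stage whose
#' artifacts already exist with a matching configuration hash is skipped
#' (provenance in `provenance.json`). Each artifact therefore carries full
#' provenance: the configuration and the per-stage RNG seeds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage-progress messages.
#' @return Invisibly, a list with the main in-memory results (`model`,
#'   `mae_energy`, `mae_charge`, `trajectory` and artifact paths).
#' @export
run_pipeline <- function(config = run_config(), out_dir = "krigwater_run",
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  prov_file <- file.path(out_dir, "provenance.json")
  prov <- if (file.exists(prov_file))
    jsonlite::read_json(prov_file, simplifyVector = TRUE) else list()
  fresh <- function(stage, files) {
    h <- .config_hash(config, stage)
    ok <- identical(prov[[stage]], h) &&
      all(file.exists(file.path(out_dir, files)))
    if (ok) note("stage %-10s cached, skipping", stage)
    !ok
  }
  done <- function(stage) {
    prov[[stage]] <<- .config_hash(config, stage)
    jsonlite::write_json(prov, prov_file, auto_unbox = TRUE)
  }
  jsonlite::write_json(config[!vapply(config, is.function, NA)],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  ens_file <- "ensemble.xyz"
  if (fresh("sample", ens_file)) {
    note("stage sample: %d configurations", config$n_samples)
    configs <- sample_configurations(seed_configuration(), config$n_samples,
                                     config$max_distortion,
                                     rng_seed = config$rng_seed,
                                     params = config$surrogate)
    write_xyz(configs, file.path(out_dir, ens_file))
    done("sample")
  }
  configs <- configurations_from_xyz(read_xyz(file.path(out_dir, ens_file)))

  lab_file <- "labelled.csv"
  if (fresh("label", lab_file)) {
    note("stage label: surrogate oracle")
    labelled <- label_ensemble(configs, config$surrogate,
                               seed = config$rng_seed + 1L)
    utils::write.csv(as_label_table(labelled),
                     file.path(out_dir, lab_file), row.names = FALSE)
    done("label")
  }
  labelled <- label_ensemble(configs, config$surrogate,
                             seed = config$rng_seed + 1L)

  policy <- filter_policy(config$charge_tolerance,
                          config$integration_error_threshold)
  kept <- filter_ensemble(labelled, policy)
  note("stage filter: retained %d / %d", length(kept), length(labelled))
  sp <- split_train_validation(kept, config$n_train,
                               rng_seed = config$rng_seed + 2L)

  model_file <- "model.json"
  if (fresh("train", model_file)) {
    note("stage train: N_trn = %d", config$n_train)
    model <- train_water_model(sp$train, optimize_p = config$optimize_p,
                               pso = config$pso,
                               rng_seed = config$rng_seed + 3L)
    write_water_model(model, file.path(out_dir, model_file))
    done("train")
  }
  model <- read_water_model(file.path(out_dir, model_file))

  val_file <- "validation.csv"
  ee <- validation_errors(model, sp$validation, "energy")
  qe <- validation_errors(model, sp$validation, "net_charge")
  utils::write.csv(data.frame(error_energy_kjmol = sort(ee),
                              error_charge_me = sort(qe),
                              cum_pct = 100 * seq_along(ee) / length(ee)),
                   file.path(out_dir, val_file), row.names = FALSE)
  note("stage validate: MAE %.3f kJ/mol, %.3f me", mae(ee), mae(qe))

  traj_file <- "trajectory.xyz"; elog_file <- "energies.csv"
  if (fresh("simulate", c(traj_file, elog_file))) {
    note("stage simulate: N_mol = %d, L = %d, %d steps",
         config$n_mol, config$L, config$n_steps)
    traj <- run_simulation(model, n_mol = config$n_mol, L = config$L,
                           n_steps = config$n_steps, dt = config$dt,
                           temperature = config$temperature,
                           collision_rate = config$collision_rate,
                           rigid = config$rigid,
                           rng_seed = config$rng_seed + 4L)
    write_trajectory_xyz(traj, file.path(out_dir, traj_file))
    utils::write.csv(traj$energy, file.path(out_dir, elog_file),
                     row.names = FALSE)
    done("simulate")
  } else traj <- NULL
  if (is.null(traj)) {
    frames <- read_xyz(file.path(out_dir, traj_file))
    traj <- list(frames = lapply(frames, `[[`, "coords"),
                 species = frames[[1]]$elements,
                 molecule = rep(seq_len(config$n_mol), each = 3),
                 energy = utils::read.csv(file.path(out_dir, elog_file)))
  }

  if (fresh("analyze", "rdf_OO.csv")) {
    note("stage analyze: radial distribution functions")
    for (pt in c("OO", "OH", "HH")) {
      g <- rdf(traj, pt)
      utils::write.csv(as.data.frame(g),
                       file.path(out_dir, sprintf("rdf_%s.csv", pt)),
                       row.names = FALSE)
    }
    done("analyze")
  }
  invisible(list(model = model, mae_energy = mae(ee), mae_charge = mae(qe),
                 trajectory = traj, out_dir = out_dir))
}
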