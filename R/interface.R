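# Configuration, provenance and the end-to-end pipeline driver.  The exported
# functions are the package's interface; inst/scripts/graftnet-cli.R is a
# thin command-line wrapper over them.

#' Read a scenario configuration (YAML)
#'
#' Reads vessel geometry/flow and GA settings from a YAML file with optional
#' top-level sections `scenario` (fields of [vessel_state()]) and `ga`
#' (fields of [ga_config()]).
#'
#' @param path YAML file.
#' @return List with `scenario` (a [vessel_state()]) and `ga`
#'   (a [ga_config()]).
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- do.call(vessel_state, as.list(cfg$scenario))
  ga <- do.call(ga_config, as.list(cfg$ga))
  list(scenario = sc, ga = ga)
}

#' Write a run manifest
#'
#' Records the provenance needed to regenerate a pipeline output directory:
#' the command, configuration, seeds, MD5 digests of every input and output
#' file, package version and timestamp. Exactly one `manifest.json` is kept
#' per output directory.
#'
#' @param dir Output directory.
#' @param command Short command descriptor.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @param seeds Named list/vector of seeds used.
#' @param config Arbitrary configuration list stored verbatim.
#' @return Invisible path of the manifest.
#' @export
write_run_manifest <- function(dir, command, inputs = character(0),
                               outputs = character(0), seeds = list(),
                               config = list()) {
  digest <- function(paths) {
    if (length(paths) == 0) return(NULL)
    md5 <- tools::md5sum(paths)
    as.list(setNames(unname(md5), basename(paths)))
  }
  manifest <- list(command = command,
                   package = "graftnet",
                   version = as.character(utils::packageVersion("graftnet")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   seeds = seeds, config = config,
                   inputs = digest(inputs), outputs = digest(outputs))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Generates (or reads) a study-shaped dataset, runs the three-stage
#' calibration chain, screens all single and coupled gene therapies, and
#' writes tables, parameter bundles and a provenance manifest to `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param seed Master seed; stage seeds derive from it.
#' @param data_dir Optional directory of existing tables (see
#'   [read_dataset()]); when `NULL` a synthetic dataset is generated.
#' @param scenario A [vessel_state()].
#' @param noise Noise levels for the synthetic dataset.
#' @param cn_config,w_config,b_config Stage GA configurations; defaults are
#'   moderate desk-scale budgets.
#' @param n_runs Independently seeded GA runs per stage.
#' @param screen_pairs Whether to include the 10 coupled therapies.
#' @param singles_step,pair_coarse Therapy search grids.
#' @return Invisible list with the calibration results, the screen table and
#'   the output paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, data_dir = NULL,
                         scenario = vessel_state(),
                         noise = c(expression = 0.02, rates = 0.02,
                                   thickness = 0.02),
                         cn_config = ga_config(pop_multiplier = 30,
                                               generations = 80,
                                               stall_gens = 15, seed = seed),
                         w_config = ga_config(generations = 120,
                                              n_restarts = 10,
                                              restart_shrink = 0.6,
                                              sigma_end = 0.002,
                                              stall_gens = 25, seed = seed),
                         b_config = ga_config(generations = 150,
                                              n_restarts = 10,
                                              restart_shrink = 0.5,
                                              sigma_end = 0.001,
                                              stall_gens = 25, seed = seed),
                         n_runs = 1, screen_pairs = TRUE,
                         singles_step = 0.01, pair_coarse = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.null(data_dir)) {
    truth <- make_ground_truth(seed, scenario = scenario, noise = noise)
    dataset <- generate_dataset(truth)
    data_dir <- file.path(out_dir, "data")
    write_dataset(dataset, data_dir)
  } else {
    truth <- NULL
    dataset <- read_dataset(data_dir)
    inputs <- list.files(data_dir, full.names = TRUE)
  }
  grid <- dataset$grid
  cal <- calibrate_pipeline(dataset, scenario, cn_config, w_config, b_config,
                            n_runs = n_runs)
  screen <- therapy_screen(cal$hybrid, grid, singles_step = singles_step,
                           pair_coarse = pair_coarse, pairs = screen_pairs)
  params_path <- file.path(out_dir, "hybrid_parameters.json")
  save_parameters(cal$hybrid, params_path)
  screen_path <- file.path(out_dir, "therapy_screen.csv")
  utils::write.table(as.data.frame(screen), screen_path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  sim <- simulate_hybrid(cal$hybrid, NULL, grid)
  traj_path <- file.path(out_dir, "morphology.csv")
  utils::write.table(as.data.frame(sim$morphology), traj_path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  outputs <- c(params_path, screen_path, traj_path,
               list.files(file.path(out_dir, "data"), full.names = TRUE))
  write_run_manifest(out_dir, "run_pipeline", inputs = inputs,
                     outputs = outputs[file.exists(outputs)],
                     seeds = list(master = seed),
                     config = list(n_runs = n_runs,
                                   noise = as.list(noise),
                                   cn = unclass(cn_config),
                                   w = unclass(w_config),
                                   b = unclass(b_config)))
  invisible(list(truth = truth, dataset = dataset, calibration = cal,
                 screen = screen,
                 paths = list(params = params_path, screen = screen_path,
                              morphology = traj_path)))
}
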