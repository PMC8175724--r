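## Run-directory conventions: one refinement run writes one directory with
## `initial.csv` and `final.csv` (dense weight matrices), `trace.csv`
## (per-epoch objective and constraint diagnostics) and `manifest.json`
## (full configuration, seed, package version, timestamps, file list).
## Comparison commands are stateless readers over such directories, so
## many-run protocols are plain loops over seeds.

#' Run a simulation and write its outputs to a directory
#'
#' Trains a network with [refine_network()] and persists the initial and
#' final matrices, the energy trace and a JSON manifest.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Passed to [refine_network()].
#' @return The `trained_network`, invisibly; side effect: four files in
#'   `out_dir`.
#' @export
run_simulation <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  net <- refine_network(config, verbose = verbose)
  files <- c(initial = "initial.csv", final = "final.csv",
             trace = "trace.csv", manifest = "manifest.json")
  write_dense_csv(net$initial_weights, file.path(out_dir, files["initial"]))
  write_dense_csv(net$weights, file.path(out_dir, files["final"]))
  utils::write.csv(net$trace, file.path(out_dir, files["trace"]),
                   row.names = FALSE)
  manifest <- list(
    config = config_as_list(config),
    e_a_initial = net$e_a_initial,
    e_a_floor = net$e_a_floor,
    package_version = as.character(utils::packageVersion("connergy")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, files["manifest"]),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(net)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$n_sigma <- if (is.null(out$n_sigma)) "none" else out$n_sigma
  out$alpha <- if (is.null(out$alpha)) "none" else out$alpha
  out
}

config_from_list <- function(x) {
  none_null <- function(v) if (is.null(v) || identical(v, "none")) NULL else v
  simulation_config(
    n_nodes = x$n_nodes, n_epochs = x$n_epochs,
    batches_per_epoch = x$batches_per_epoch, n_signals = x$n_signals,
    learning_rate = x$learning_rate, init_mean = x$init_mean,
    init_std = x$init_std, n_sigma = none_null(x$n_sigma),
    alpha = none_null(x$alpha), p_max = x$p_max,
    activity_form = x$activity_form, sign_scheme = x$sign_scheme,
    transpose_mode = x$transpose_mode, seed = x$seed)
}

#' Read a simulation configuration from a flat JSON or YAML file
#'
#' The file holds a flat key-value mapping whose keys mirror the
#' [simulation_config()] arguments exactly (unknown keys are an error;
#' missing keys take the defaults). `n_sigma` and `alpha` accept the
#' string `"none"` for the unconstrained settings. The format is chosen by
#' extension: `.json`, or `.yaml`/`.yml` (requires the `yaml` package).
#'
#' @param path Path to the configuration file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in c("n_sigma", "alpha"))
    if (k %in% names(x) && identical(x[[k]], "none"))
      x[k] <- list(NULL)  # pass an explicit NULL, not a dropped argument
  do.call(simulation_config, x)
}

#' Load a simulation run directory
#'
#' @param dir A directory written by [run_simulation()].
#' @return List with `initial`, `final` (matrices), `trace` (data frame)
#'   and `manifest` (list, with `config` restored as a
#'   [simulation_config()]).
#' @export
load_run <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop(sprintf("not a run directory (no manifest.json): %s", dir),
         call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  manifest$config <- config_from_list(manifest$config)
  list(initial = read_dense_csv(file.path(dir, "initial.csv")),
       final = read_dense_csv(file.path(dir, "final.csv")),
       trace = utils::read.csv(file.path(dir, "trace.csv")),
       manifest = manifest)
}

## Resolve a CLI input (run directory or connectome file) to a matrix.
input_matrix <- function(path, degree_product = FALSE, use_initial = FALSE) {
  W <- if (dir.exists(path)) {
    run <- load_run(path)
    if (use_initial) run$initial else run$final
  } else {
    read_connectome(path)$matrix
  }
  if (degree_product) W <- degree_product_weights(W)
  W
}
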