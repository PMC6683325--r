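# End-to-end pipeline driver: simulate -> fit-maturity -> score, with a
# machine-readable run manifest. All randomness flows from the single
# configured seed; identical config + seed gives byte-identical outputs.

#' Pipeline run configuration
#'
#' Bundles the seed, output directory and per-stage parameters for
#' [run_pipeline()]. A configuration round-trips losslessly through YAML via
#' [write_run_config()] / [load_run_config()].
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Single integer seed for every source of randomness.
#' @param cohort Named list of [cohort_config()] arguments for the healthy
#'   reference cohort.
#' @param test_cohort Named list of [cohort_config()] arguments for the
#'   cohort to score (e.g. with `immaturity_factor < 1`); `NULL` scores the
#'   healthy cohort itself.
#' @param model Named list of model-stage settings: `num_trees`,
#'   `max_features`, `n_folds`.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, cohort = list(),
                       test_cohort = NULL,
                       model = list()) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    cohort = cohort,
    test_cohort = test_cohort,
    model = modifyList(list(num_trees = 500, max_features = 30, n_folds = 5),
                       model)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the simulate / fit-maturity / score pipeline
#'
#' Generates a healthy reference cohort, fits, sparsifies and calibrates the
#' microbiota-age model, scores the test cohort (or the healthy cohort
#' itself), and writes every stage artifact plus a JSON manifest (stages,
#' seed, package version, md5 of each output) into `config$out_dir`. Outputs
#' are written atomically after all stages succeed, so a failing run leaves
#' no partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # stage 1: simulate
  cohort_args <- modifyList(list(seed = seed), config$cohort)
  cc <- do.call(cohort_config, cohort_args)
  tr <- taxon_trajectories(cc$n_taxa, cc$n_discriminatory, seed = seed)
  healthy <- generate_healthy_cohort(cc, tr)
  if (!is.null(config$test_cohort)) {
    test_args <- modifyList(list(seed = seed + 1), config$test_cohort)
    test <- generate_immature_cohort(do.call(cohort_config, test_args), tr)
  } else {
    test <- healthy
  }

  # stage 2: fit-maturity
  model <- fit_age_model(healthy$table, healthy$meta,
                         num_trees = config$model$num_trees, seed = seed)
  model <- sparsify(model, max_features = config$model$max_features,
                    n_folds = config$model$n_folds)
  model <- calibrate(model, n_folds = config$model$n_folds)

  # stage 3: score
  scores <- score_samples(model, test$table, test$meta)

  # write everything at the end; each file atomically
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  write_abundance_table(healthy$table, path("healthy_table.tsv"), seed = seed)
  write_gm_tsv(healthy$meta, path("healthy_meta.tsv"), seed = seed)
  write_abundance_table(test$table, path("test_table.tsv"), seed = seed)
  write_gm_tsv(test$meta, path("test_meta.tsv"), seed = seed)
  save_maturity_model(model, path("model.json"))
  write_gm_tsv(scores, path("scores.tsv"), seed = seed)

  files <- c("healthy_table.tsv", "healthy_meta.tsv", "test_table.tsv",
             "test_meta.tsv", "model.json", "scores.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutmaturity")),
    seed = seed,
    stages = c("simulate", "fit-maturity", "score"),
    outputs = as.list(setNames(unname(tools::md5sum(vapply(files, path,
                                                           character(1)))),
                               files))
  )
  jtmp <- path(paste0("manifest.json.tmp", Sys.getpid()))
  jsonlite::write_json(manifest, jtmp, auto_unbox = TRUE, digits = NA)
  file.rename(jtmp, path("manifest.json"))

  invisible(list(healthy = healthy, test = test, model = model,
                 scores = scores, manifest = manifest))
}
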