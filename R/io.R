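#' Serialize and restore problem instances
#'
#' Instances are stored as a single JSON document with the disease-subset
#' keys of the attributed sign configurations encoded as sorted
#' comma-joined indices (`""` for the all-healthy hypothesis). Round trips
#' are lossless.
#'
#' @param instance A `problem_instance`.
#' @param path File path.
#' @return `read_instance` returns a `problem_instance`.
#' @export
write_instance <- function(instance, path) {
  x <- unclass(instance)
  # The all-healthy key is the empty string, which R named lists cannot
  # carry through jsonlite; emit a sentinel and rewrite it in the text.
  sentinel <- ".empty-hypothesis."
  nm <- names(x$attributed_signs)
  names(x$attributed_signs)[nm == ""] <- sentinel
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- readLines(path)
  writeLines(gsub(paste0('"', sentinel, '"'), '""', txt, fixed = TRUE), path)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$graph$one_factors <- lapply(x$graph$one_factors, function(f) {
    list(disease = as.integer(f$disease), signs = as.integer(f$signs))
  })
  x$graph$two_factors <- lapply(x$graph$two_factors, function(f) {
    list(pair = as.integer(f$pair), signs = as.integer(f$signs))
  })
  x$attributed_signs <- lapply(x$attributed_signs, as.integer)
  x$n_signs <- as.integer(x$n_signs)
  x$n_diseases <- as.integer(x$n_diseases)
  x$seed <- as.integer(x$seed)
  structure(x, class = "problem_instance")
}

#' Serialize and restore fitted models
#'
#' @param model A `maxent_model`.
#' @param path File path.
#' @return `read_model` returns a `maxent_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$n_signs <- as.integer(x$n_signs)
  x$n_diseases <- as.integer(x$n_diseases)
  x$leak_fields <- as.numeric(x$leak_fields)
  x$prior_fields <- as.numeric(x$prior_fields)
  x$prior_prob <- as.numeric(x$prior_prob)
  x$graph$one_factors <- lapply(x$graph$one_factors, function(f) {
    list(disease = as.integer(f$disease), signs = as.integer(f$signs))
  })
  x$graph$two_factors <- lapply(x$graph$two_factors, function(f) {
    list(pair = as.integer(f$pair), signs = as.integer(f$signs))
  })
  x$one_couplings <- lapply(x$one_couplings, function(f) {
    list(disease = as.integer(f$disease), signs = as.integer(f$signs),
         K = as.numeric(f$K))
  })
  x$two_couplings <- lapply(x$two_couplings, function(f) {
    list(pair = as.integer(f$pair), signs = as.integer(f$signs),
         K = as.numeric(f$K))
  })
  structure(x, class = "maxent_model")
}

#' Serialize a trajectory
#'
#' Writes a JSON document with the run metadata and per-step records, and
#' optionally a flat CSV of the step table for downstream metrics.
#'
#' @param trajectory A `trajectory`.
#' @param path JSON file path.
#' @param csv_path Optional CSV path for the step table.
#' @export
write_trajectory <- function(trajectory, path, csv_path = NULL) {
  x <- unclass(trajectory)
  x$initial_state <- unclass(x$initial_state)
  x$params <- unclass(x$params)
  x$marginals <- apply(x$marginals, 1L, identity, simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(trajectory$steps, csv_path, row.names = FALSE)
  }
  invisible(path)
}

config_defaults <- function() {
  list(n_signs = NULL, n_diseases = NULL, graph = NULL, order = "D2S1",
       expected_present = 2, n_present = 2, mode = "diags2",
       strategy = "greedy", n_steps = NULL, n_initial = 0L, lambda_P = 0,
       lambda_C = 0, p_th = 0.9, n_realizations = 100L, mc = NULL,
       seed = 1L, out_dir = NULL)
}

mc_defaults <- function() {
  list(n_total = 20000L, n_eq = 2000L, n_sample = 20L, beta = 1,
       beta_start = 1, beta_end = 10, n_annealing = 5000L)
}

#' Build or load an experiment configuration
#'
#' `experiment_config()` validates a set of named settings against the
#' schema and fills defaults (threshold `p_th = 0.9`, prior expecting two
#' present diseases, the reference Monte Carlo budgets when `mc:` is
#' present). `load_config()` reads the same structure from a YAML file;
#' `dump_config()` writes one back, so load-dump-load is idempotent.
#'
#' @param ... Named settings; unknown names raise a validation error that
#'   lists the offending fields.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(...) {
  given <- list(...)
  if (length(given) == 1L && is.list(given[[1]]) && is.null(names(given))) {
    given <- given[[1]]
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0L) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, given, keep.null = TRUE)
  for (req in c("n_signs", "n_diseases", "n_steps")) {
    if (is.null(cfg[[req]])) stopf("configuration field '%s' is required", req)
  }
  if (!cfg$order %in% c("D2S1", "D1S1")) stopf("order must be D2S1 or D1S1")
  if (!cfg$mode %in% c("diags1", "diags2")) stopf("mode must be diags1 or diags2")
  if (!cfg$strategy %in% c("greedy", "random")) {
    stopf("strategy must be greedy or random")
  }
  if (cfg$p_th <= 0.5 || cfg$p_th >= 1) stopf("p_th must lie in (1/2, 1)")
  if (!is.null(cfg$mc)) {
    mcu <- setdiff(names(cfg$mc), names(mc_defaults()))
    if (length(mcu) > 0L) {
      stopf("unknown mc field(s): %s", paste(mcu, collapse = ", "))
    }
    cfg$mc <- utils::modifyList(mc_defaults(), cfg$mc)
  }
  cfg$n_initial <- as.integer(cfg$n_initial)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("configuration file not found: %s", path)
  experiment_config(yaml::read_yaml(path))
}

#' @rdname experiment_config
#' @param cfg An `experiment_config`.
#' @export
dump_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}
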