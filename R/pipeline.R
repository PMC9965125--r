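# End-to-end orchestration: a fully-defaulted run configuration, the
# descriptor stage and the model stage, each writing its outputs and a
# reproducibility manifest.

#' Build a run configuration
#'
#' Every field has a default; the effective configuration is serialised
#' into each run's manifest so outputs are reproducible.
#'
#' @param manifest path to a compound manifest CSV (columns id, smiles,
#'   optional formula/role); \code{NULL} uses the packaged compound set.
#' @param charge_scheme charge scheme name.
#' @param probe,n_points surface parameters.
#' @param descriptors descriptor names to compute.
#' @param k model size for descriptor selection.
#' @param transform response transform tag.
#' @param response_scale \code{"fraction"} (divide percent responses by
#'   100 before fitting) or \code{"percent"}.
#' @param cv_folds,cv_repeats,seed cross-validation settings.
#' @param output_dir directory for stage outputs.
#' @return a \code{run_config} list.
#' @export
run_config <- function(manifest = NULL, charge_scheme = "gasteiger",
                       probe = 1.4, n_points = 960L,
                       descriptors = descriptor_catalogue(), k = 3L,
                       transform = "identity",
                       response_scale = "fraction",
                       cv_folds = 3L, cv_repeats = 200L, seed = 1L,
                       output_dir = tempfile("clickqsar_run_")) {
  structure(list(manifest = manifest, charge_scheme = charge_scheme,
                 probe = probe, n_points = as.integer(n_points),
                 descriptors = descriptors, k = as.integer(k),
                 transform = transform, response_scale = response_scale,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

.write_run_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    config = unclass(config),
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("clickqsar")),
    r_version = R.version.string)
  path <- file.path(config$output_dir, paste0(stage, "_manifest.yml"))
  yaml::write_yaml(manifest, path)
  path
}

#' Run the descriptor stage
#'
#' Loads the compound manifest (or the packaged compound set), computes
#' the configured descriptors for every compound and writes the descriptor
#' CSV, its provenance sidecar and a run manifest. Per-compound failures
#' are collected; the stage fails only if every compound fails.
#'
#' @param config a \code{run_config}.
#' @return path of the descriptor CSV, with the table attached as the
#'   \code{"table"} attribute.
#' @export
run_descriptors <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- if (is.null(config$manifest)) {
    load_fixture_set()
  } else {
    man <- read_manifest(config$manifest)
    if (!nrow(man)) stop("empty compound manifest: ", config$manifest)
    lapply(seq_len(nrow(man)), function(k) {
      list(id = man$id[k],
           molecule = parse_structure(man$smiles[k], "smiles",
                                      id = man$id[k]))
    })
  }
  tab <- compute_descriptor_table(
    compounds, descriptors = config$descriptors, probe = config$probe,
    n_points = config$n_points, scheme = config$charge_scheme,
    seed = config$seed, on_error = "collect")
  failures <- attr(tab, "failures")
  if (length(failures)) {
    message("descriptor failures (", length(failures), "):\n",
            paste(failures, collapse = "\n"))
  }
  csv <- file.path(config$output_dir, "descriptors.csv")
  write_descriptor_csv(tab, csv)
  .write_run_manifest(config, "descriptors",
                      inputs = list(manifest = config$manifest %||% "packaged"),
                      outputs = list(csv = csv))
  attr(csv, "table") <- tab
  csv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the model stage
#'
#' Reads a descriptor CSV and a response table, selects the best
#' k-descriptor multilinear model, attaches leave-one-out and
#' leave-many-out statistics and writes the model file plus an
#' observed-versus-predicted report.
#'
#' @param config a \code{run_config}.
#' @param descriptor_csv path from \code{\link{run_descriptors}}.
#' @param response named numeric vector (names = compound ids) or
#'   data.frame with columns \code{id}, \code{value}.
#' @return path of the model file, with the fitted \code{qsar_model}
#'   attached as the \code{"model"} attribute and the
#'   observed-vs-predicted table as \code{"report"}.
#' @export
run_fit <- function(config, descriptor_csv, response) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_descriptor_csv(descriptor_csv)
  if (is.data.frame(response)) {
    response <- stats::setNames(response$value, response$id)
  }
  ids <- intersect(rownames(tab), names(response))
  if (length(ids) < config$k + 2) {
    stop("too few compounds with both descriptors and response (",
         length(ids), ")")
  }
  if (config$k > ncol(tab)) {
    stop("model size k = ", config$k, " exceeds descriptor count ",
         ncol(tab))
  }
  y <- response[ids]
  if (config$response_scale == "fraction") y <- y / 100
  X <- descriptor_matrix(tab[ids, , drop = FALSE], ids = ids, response = y,
                         response_name = "response",
                         transform = config$transform)
  model <- bmlr_select(X, k = config$k, cv_seed = config$seed)
  model$r2cv_lmo <- lmo_cv(X, model$descriptors, n_groups = config$cv_folds,
                           n_repeats = config$cv_repeats,
                           seed = config$seed)
  model_file <- file.path(config$output_dir, "model.yml")
  write_qsar_model(model, model_file)
  pred <- predict(model, as.matrix(tab[ids, , drop = FALSE]))
  report <- data.frame(id = ids, observed = as.numeric(y),
                       predicted = as.numeric(pred))
  report_file <- file.path(config$output_dir, "observed_vs_predicted.csv")
  utils::write.csv(report, report_file, row.names = FALSE)
  .write_run_manifest(config, "fit",
                      inputs = list(descriptor_csv = descriptor_csv),
                      outputs = list(model = model_file,
                                     report = report_file))
  attr(model_file, "model") <- model
  attr(model_file, "report") <- report
  model_file
}
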