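# Model-bundle serialization and run manifests. A bundle is a directory with
# a JSON manifest (member kinds, chosen hyperparameters, seed, normalization
# parameters) next to the serialized model objects, so trained pipelines can
# be reloaded and runs replayed exactly.

#' Save a fitted model to a bundle directory
#'
#' @param object a `qsar_ensemble` or `tox_model`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "denovoscreen",
                   version = as.character(utils::packageVersion("denovoscreen")),
                   class = class(object)[1],
                   created = format(Sys.time(), tz = "UTC"))
  if (inherits(object, "qsar_ensemble")) {
    manifest$members <- lapply(seq_along(object$members), function(i) {
      list(kind = object$members[[i]]$kind,
           featurization = object$specs[[i]]$featurization,
           hyper = object$members[[i]]$hyper)
    })
    manifest$seed <- object$seed
    manifest$n_train <- object$n_train
    manifest$normalization <- object$normalization$params
  } else if (inherits(object, "tox_model")) {
    manifest$tasks <- object$tasks
    manifest$seed <- object$seed
    manifest$n_train <- object$n_train
  } else {
    stop("unsupported object class: ", class(object)[1])
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(object, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a model bundle
#'
#' @param dir a directory written by [save_bundle()].
#' @return the stored model object.
#' @export
load_bundle <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) {
    stop("not a model bundle (missing model.rds): ", dir)
  }
  readRDS(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its command, configuration snapshot, seeds and
#' input/output paths, so the run can be replayed byte-identically.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config configuration list (seeds included).
#' @param inputs,outputs named paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config, inputs = list(),
                               outputs = list()) {
  manifest <- list(command = command,
                   package = "denovoscreen",
                   version = as.character(utils::packageVersion("denovoscreen")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = config,
                   inputs = inputs,
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
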