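# Model checkpoints: R-native serialisation of the weights plus a JSON
# sidecar with the full configuration, so a run can be reproduced or
# inspected without loading the binary blob.

#' Save a model checkpoint
#'
#' Writes `<path>` (RDS with parameters, batch-norm statistics and
#' configuration) and `<path>.json` (human-readable configuration sidecar).
#'
#' @param model An `mceegnet_model`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mceegnet_model"))
  payload <- list(cfg = model$cfg, params = model$params, bn = model$bn,
                  package_version = as.character(utils::packageVersion("mceegnet")))
  saveRDS(payload, path)
  sidecar <- list(
    mode = model$cfg$mode, n_classes = model$cfg$n_classes,
    branch = unclass(model$cfg$branch),
    feature_dim = feature_dim(model$cfg),
    n_parameters = count_parameters(model$cfg),
    package_version = payload$package_version
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return An `mceegnet_model`.
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  structure(list(cfg = payload$cfg, params = payload$params, bn = payload$bn,
                 ws = new.env(parent = emptyenv())),
            class = "mceegnet_model")
}
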