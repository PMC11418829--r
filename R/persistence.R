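#' Persist a pipeline object with a JSON sidecar
#'
#' Flow sequences, kinematic stacks and fused descriptors are saved as
#' compressed serialized archives (`<path>.rds`) together with a plain-JSON
#' sidecar (`<path>.json`) carrying the identifying metadata (patient,
#' slice, label, channels, backend settings) for auditability.
#'
#' @param x A `flow_sequence`, `kinematic_stack`, `fused_descriptor` or
#'   `cine_sequence`.
#' @param path Output path without extension.
#' @return Invisibly, the `.rds` path.
#' @export
save_archive <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  rds <- paste0(path, ".rds")
  saveRDS(x, rds, compress = "gzip")
  meta <- list(class = class(x)[1],
               patient_id = x$patient_id %||% NULL,
               slice_index = x$slice_index %||% NULL,
               label = x$label %||% NULL,
               channel_names = x$channel_names %||% NULL,
               kinematic_order = x$kinematic_order %||% NULL,
               frame_indices = x$frame_indices %||% NULL,
               backend = x$config$backend %||% NULL)
  if (inherits(x, "conv3d_net")) {
    # cross-framework auditability: dump the layer stack alongside weights
    meta$classes <- x$classes
    meta$seed <- x$seed
    meta$layers <- lapply(unname(x$spec$layers), function(ly)
      list(name = ly$name, kind = ly$kind,
           out_shape = ly$out_shape, params = ly$params,
           stride = ly$stride %||% NULL))
  }
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(rds)
}

#' Write a pipeline configuration as YAML
#'
#' Serializes every stage default of a [pipeline_config] (flow backend,
#' channels, network and forest settings, aggregation rule) to a plain YAML
#' file, so a run is fully described by its config file plus a seed.
#'
#' @param config A [pipeline_config].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Read a pipeline configuration written by [save_pipeline_config]
#'
#' @param path YAML path.
#' @return A [pipeline_config].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    target_len = y$target_len, size = y$size,
    channels = unlist(y$channels), eps = y$eps,
    flow = do.call(flow_config, y$flow[setdiff(names(y$flow), "backend")]),
    net = do.call(conv3d_config, y$net[setdiff(names(y$net), "batch")]),
    forest = do.call(forest_config, y$forest),
    mode = y$mode, embedding_layer = y$embedding_layer,
    aggregate = y$aggregate)
}

#' Load an archive written by [save_archive]
#'
#' @param path Path without extension (as given to [save_archive]).
#' @return The restored object.
#' @export
load_archive <- function(path) readRDS(paste0(path, ".rds"))
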