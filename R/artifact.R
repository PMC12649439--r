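# Model artifact: everything inference needs, in one self-describing,
# versioned JSON file. Weights are stored as base64-encoded little-endian
# IEEE doubles (exact round-trip); gesture map, scaler and sensor
# configuration travel alongside as plain JSON.

ARTIFACT_SCHEMA <- "gesturekit-artifact/1"

#' Construct a model artifact
#'
#' Bundles trained weights with the gesture-to-class map, the fitted scaler
#' parameters and the sensor configuration, so a stored model can be
#' deployed without any context beyond the file itself.
#'
#' @param weights Named list of parameter matrices/vectors.
#' @param model_cfg The `model_config` the weights belong to.
#' @param gesture_map Named integer vector, gesture label to 0-based class
#'   index; must be a bijection onto `0:(n_classes-1)`.
#' @param scaler `scaler_params` fitted on the training data.
#' @param sensor_config List with `n_channels` and `sampling_rate`.
#' @param user_id User the model belongs to.
#' @param created Creation timestamp string (defaults to now, UTC).
#' @return An object of class `model_artifact`.
#' @export
model_artifact <- function(weights, model_cfg, gesture_map, scaler,
                           sensor_config, user_id = NA_character_,
                           created = format(Sys.time(), tz = "UTC")) {
  idx <- sort(as.integer(gesture_map))
  if (!identical(idx, seq_along(gesture_map) - 1L)) {
    stop("gesture_map must be a bijection onto 0:(n_classes-1)")
  }
  if (length(scaler$mean) != sensor_config$n_channels) {
    stop("scaler channel count must equal sensor channel count")
  }
  structure(
    list(schema_version = ARTIFACT_SCHEMA, weights = weights,
         model_cfg = model_cfg, gesture_map = gesture_map, scaler = scaler,
         sensor_config = sensor_config, user_id = user_id, created = created),
    class = "model_artifact"
  )
}

#' @export
print.model_artifact <- function(x, ...) {
  cat(sprintf(
    "<model_artifact> user %s: %d classes (%s), %d ch @ %g Hz, schema %s\n",
    x$user_id, length(x$gesture_map),
    paste(names(sort(x$gesture_map)), collapse = ", "),
    x$sensor_config$n_channels, x$sensor_config$sampling_rate,
    x$schema_version))
  invisible(x)
}

encode_blob <- function(x) {
  list(dim = if (is.null(dim(x))) length(x) else dim(x),
       data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                            size = 8, endian = "little")))
}

decode_blob <- function(b) {
  v <- readBin(jsonlite::base64_dec(b$data), "numeric",
               n = prod(unlist(b$dim)), size = 8, endian = "little")
  if (length(b$dim) > 1 || (is.list(b$dim) && length(unlist(b$dim)) > 1)) {
    dim(v) <- unlist(b$dim)
  }
  v
}

#' Save / load a model artifact
#'
#' `save_artifact()` writes a single versioned JSON file;
#' `load_artifact()` restores it to an artifact whose predictions are
#' bit-identical to the original's. A schema-version mismatch or a damaged
#' file raises an explicit error rather than misloading.
#'
#' @param artifact A `model_artifact`.
#' @param path File path.
#' @return `save_artifact()` returns `path` invisibly; `load_artifact()`
#'   returns a `model_artifact`.
#' @export
save_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "model_artifact"))
  payload <- list(
    schema_version = artifact$schema_version,
    user_id = artifact$user_id,
    created = artifact$created,
    gesture_map = as.list(artifact$gesture_map),
    scaler = list(mean = artifact$scaler$mean, sd = artifact$scaler$sd,
                  epsilon = artifact$scaler$epsilon,
                  degenerate = artifact$scaler$degenerate),
    sensor_config = artifact$sensor_config,
    model_cfg = unclass(artifact$model_cfg),
    weights = lapply(artifact$weights, encode_blob)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) {
                        stop("cannot load artifact from ", path, ": ",
                             conditionMessage(e))
                      })
  if (!identical(payload$schema_version, ARTIFACT_SCHEMA)) {
    stop("artifact schema version '", payload$schema_version,
         "' is incompatible with supported version '", ARTIFACT_SCHEMA, "'")
  }
  mc <- payload$model_cfg
  cfg <- model_config(
    n_channels = mc$n_channels, n_classes = mc$n_classes,
    window_len = mc$window_len,
    conv_blocks = lapply(mc$conv_blocks, function(b) unlist(b)),
    dense_widths = unlist(mc$dense_widths)
  )
  scaler <- structure(
    list(mean = unlist(payload$scaler$mean), sd = unlist(payload$scaler$sd),
         epsilon = payload$scaler$epsilon,
         degenerate = unlist(payload$scaler$degenerate)),
    class = "scaler_params"
  )
  weights <- lapply(payload$weights, decode_blob)
  model_artifact(
    weights = weights, model_cfg = cfg,
    gesture_map = unlist(payload$gesture_map),
    scaler = scaler,
    sensor_config = list(
      n_channels = as.integer(payload$sensor_config$n_channels),
      sampling_rate = as.numeric(payload$sensor_config$sampling_rate)),
    user_id = payload$user_id, created = payload$created
  )
}
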