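#' Assemble a pipeline configuration
#'
#' Collects every tunable of the simulate -> segment -> histogram -> compare
#' pipeline in one validated list that can be written to and read from YAML.
#' Defaults mirror the acquisition and analysis settings the pipeline models:
#' cells gated to 18--38 um equivalent diameter, random 1000x750-pixel
#' analysis windows, significance at alpha = 0.05.
#'
#' @param generator Generator settings, see [generator_params()].
#' @param segmentation Named list overriding [segmentation_params()].
#' @param crop Named list: `enabled` (default `FALSE`), `width_px` (1000),
#'   `height_px` (750).
#' @param kde Named list: `n_grid` (512), `bandwidth` (`NULL` = normal
#'   reference rule).
#' @param statistics Named list: `alpha` (0.05), `bonferroni` (`FALSE`).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_params(),
                            segmentation = list(),
                            crop = list(),
                            kde = list(),
                            statistics = list(),
                            seed = 1L) {
  crop <- utils::modifyList(
    list(enabled = FALSE, width_px = 1000L, height_px = 750L), crop)
  kde <- utils::modifyList(list(n_grid = 512L, bandwidth = NULL), kde)
  statistics <- utils::modifyList(
    list(alpha = 0.05, bonferroni = FALSE), statistics)
  segmentation <- do.call(segmentation_params, segmentation)

  if (crop$width_px < 1L || crop$height_px < 1L) {
    abort("crop dimensions must be >= 1.")
  }
  if (statistics$alpha <= 0 || statistics$alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  structure(
    list(generator = generator, segmentation = segmentation, crop = crop,
         kde = kde, statistics = statistics, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  gen <- raw$generator %||% list()
  if (!is.null(gen$fold_changes)) gen$fold_changes <- unlist(gen$fold_changes)
  if (!is.null(gen$diameter_range_um)) {
    gen$diameter_range_um <- as.numeric(unlist(gen$diameter_range_um))
  }
  pipeline_config(
    generator = do.call(generator_params, gen),
    segmentation = raw$segmentation %||% list(),
    crop = raw$crop %||% list(),
    kde = raw$kde %||% list(),
    statistics = raw$statistics %||% list(),
    seed = raw$seed %||% 1L
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- strip_classes(config)
  # named atomic vectors lose their names in YAML; emit a map instead
  out$generator$fold_changes <- as.list(out$generator$fold_changes)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain nested lists for serialization (yaml/json writers do not understand
# the parameter classes).
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

# Fan one master seed out to independent per-stage streams. A fixed affine
# map keeps every derived seed a valid 32-bit integer and makes each stage
# independently reproducible from the master seed alone.
derive_seed <- function(master, stage) {
  stage_id <- match(stage, c("simulate", "segment", "histogram", "compare",
                             "crop", "flow"))
  if (is.na(stage_id)) abort(paste0("unknown stage: ", stage))
  as.integer((as.numeric(master) * 48271 + stage_id * 1299709) %% 2147483647)
}
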