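#' Pipeline stages
#'
#' Each stage reads its inputs from and writes its outputs to `out_dir`, so
#' stages can be run individually or chained by [run_all()]; run
#' individually on the same inputs they reproduce the corresponding
#' [run_all()] slice bit-for-bit. Per-stage RNG streams are derived from the
#' master seed by a fixed map, making every stage independently
#' reproducible.
#'
#' * `stage_simulate()` renders the synthetic experiment: `images/*.tif`
#'   (32-bit float), `masks/*.tif` (16-bit labels), `truth.csv`,
#'   `flow_events.csv`.
#' * `stage_segment()` segments every image under `images/`: `cells.csv`
#'   plus per-image `thresholds.csv`.
#' * `stage_histogram()` pools cells/events per group x modality:
#'   `summaries.csv`, `kde_curves.csv`, `rel_changes.csv`.
#' * `stage_compare()` runs the group tests per modality and joins the
#'   modalities: `tests.csv`, `concordance.csv`, `report.txt`.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @param out_dir Run directory.
#' @return A named list of output paths and row counts, invisibly.
#' @name pipeline_stages
NULL

as_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  config
}

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, out_dir) {
  config <- as_config(config)
  gp <- config$generator
  gp$seed <- derive_seed(config$seed, "simulate")
  exp <- generate_experiment(gp)
  img_dir <- file.path(out_dir, "images")
  mask_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(exp$images)) {
    write_image(exp$images[[id]], file.path(img_dir, paste0(id, ".tif")))
    write_label_mask(exp$masks[[id]], file.path(mask_dir, paste0(id, ".tif")))
  }
  write_table_csv(exp$truth, file.path(out_dir, "truth.csv"))
  write_table_csv(exp$flow_events, file.path(out_dir, "flow_events.csv"))
  invisible(list(
    images = length(exp$images),
    cells_true = nrow(exp$truth),
    flow_events = nrow(exp$flow_events),
    outputs = c(file.path(out_dir, "truth.csv"),
                file.path(out_dir, "flow_events.csv"))
  ))
}

# Group label for an image: from truth.csv when present, else the image-id
# prefix before "_imgNN".
image_groups <- function(image_ids, out_dir) {
  truth_path <- file.path(out_dir, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- read_table_csv(truth_path)
    map <- unique(truth[, c("image_id", "group")])
    grp <- map$group[match(image_ids, map$image_id)]
    if (!anyNA(grp)) return(grp)
  }
  sub("_img[0-9]+$", "", image_ids)
}

#' @rdname pipeline_stages
#' @export
stage_segment <- function(config, out_dir) {
  config <- as_config(config)
  img_dir <- file.path(out_dir, "images")
  paths <- sort(list.files(img_dir, pattern = "\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (length(paths) == 0L) {
    abort(paste0("stage segment: no images found under ", img_dir))
  }
  crop_seed <- derive_seed(config$seed, "crop")
  cells <- list(); thresholds <- list()
  for (i in seq_along(paths)) {
    img <- read_image(paths[i], config$generator$pitch_um_per_px,
                      config$generator$channel)
    if (isTRUE(config$crop$enabled)) {
      img <- random_crop(img, config$crop$width_px, config$crop$height_px,
                         seed = (crop_seed + i) %% 2147483647)
      img$image_id <- sub("_crop$", "", img$image_id)
    }
    seg <- segment_image(img, config$segmentation)
    cells[[i]] <- seg$cells
    thresholds[[i]] <- tibble(image_id = img$image_id,
                              threshold = seg$threshold,
                              n_cells = nrow(seg$cells),
                              n_removed = seg$n_removed)
  }
  cells <- dplyr::bind_rows(cells)
  if (nrow(cells) == 0L) abort("stage segment: no cells identified.")
  cells$group <- image_groups(cells$image_id, out_dir)
  write_table_csv(cells, file.path(out_dir, "cells.csv"))
  write_table_csv(dplyr::bind_rows(thresholds),
                  file.path(out_dir, "thresholds.csv"))
  invisible(list(images = length(paths), cells = nrow(cells),
                 cells_removed = sum(dplyr::bind_rows(thresholds)$n_removed),
                 outputs = file.path(out_dir, c("cells.csv", "thresholds.csv"))))
}

# One tidy event table pooling imaging cells and flow events.
pipeline_events <- function(out_dir) {
  cells_path <- file.path(out_dir, "cells.csv")
  if (!file.exists(cells_path)) {
    abort(paste0("missing upstream output: ", cells_path,
                 " (run the segment stage first)"))
  }
  cells <- read_table_csv(cells_path)
  ev <- event_table(cells$mean_intensity_8bit, "imaging",
                    cells$group, cells$image_id)
  flow_path <- file.path(out_dir, "flow_events.csv")
  if (file.exists(flow_path)) {
    flow <- read_table_csv(flow_path)
    ev <- dplyr::bind_rows(
      ev, flow[, c("intensity_8bit", "modality", "group", "source_id")])
  }
  ev
}

#' @rdname pipeline_stages
#' @export
stage_histogram <- function(config, out_dir) {
  config <- as_config(config)
  events <- pipeline_events(out_dir)
  summaries <- histogram_summaries(events, config$kde$n_grid,
                                   config$kde$bandwidth)
  curves <- events |>
    dplyr::group_by(.data$modality, .data$group) |>
    dplyr::reframe(kde_curve(.data$intensity_8bit, config$kde$n_grid,
                             config$kde$bandwidth))
  rel <- relative_changes(summaries, control_group = "control")
  write_table_csv(summaries, file.path(out_dir, "summaries.csv"))
  write_table_csv(curves, file.path(out_dir, "kde_curves.csv"))
  write_table_csv(rel, file.path(out_dir, "rel_changes.csv"))
  invisible(list(groups = nrow(summaries), rel_records = nrow(rel),
                 outputs = file.path(out_dir, c("summaries.csv",
                                                "kde_curves.csv",
                                                "rel_changes.csv"))))
}

#' @rdname pipeline_stages
#' @export
stage_compare <- function(config, out_dir) {
  config <- as_config(config)
  events <- pipeline_events(out_dir)
  rel_path <- file.path(out_dir, "rel_changes.csv")
  if (!file.exists(rel_path)) {
    abort(paste0("missing upstream output: ", rel_path,
                 " (run the histogram stage first)"))
  }
  rel <- read_table_csv(rel_path)
  means <- replicate_means(events)
  alpha <- config$statistics$alpha
  tests <- means |>
    dplyr::group_split(.data$modality) |>
    purrr::map(function(m) {
      t <- compare_groups(m, alpha, config$statistics$bonferroni)
      dplyr::mutate(tidy(t), modality = m$modality[1L], .before = 1L)
    }) |>
    dplyr::bind_rows()
  modalities <- unique(rel$modality)
  conc <- NULL
  if (all(c("imaging", "flow") %in% modalities)) {
    conc <- build_concordance(
      dplyr::filter(rel, .data$modality == "imaging"),
      dplyr::filter(rel, .data$modality == "flow"))
    write_table_csv(as_tibble(conc), file.path(out_dir, "concordance.csv"))
  }
  write_table_csv(tests, file.path(out_dir, "tests.csv"))

  lines <- c(
    "opticyto group comparison report",
    sprintf("alpha = %g%s", alpha,
            if (config$statistics$bonferroni) " (Bonferroni-adjusted)" else ""),
    "",
    sprintf("%s: %s = %.4f, df = (%s, %s), p = %.4g -> %s",
            tests$modality, tests$test, tests$statistic,
            format(tests$df1), format(tests$df2), tests$p_value,
            ifelse(tests$significant, "significant", "not significant"))
  )
  if (!is.null(conc)) {
    lines <- c(lines, "",
               sprintf("sign agreement between modalities: %d / %d metric x group keys",
                       sum(conc$sign_agree), nrow(conc)))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(list(tests = nrow(tests),
                 outputs = file.path(out_dir, c("tests.csv", "report.txt"))))
}

#' Run the full pipeline
#'
#' simulate -> segment -> histogram -> compare, as one reproducible run.
#' Validates the configuration up front (a configuration without groups or
#' without a control group fails before any stage runs), executes the stages
#' in order, and writes a machine-readable run manifest recording the
#' configuration snapshot, master seed, per-stage outputs and row counts.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @param out_dir Run directory (created if needed).
#' @param simulate If `FALSE`, skip the simulate stage and segment
#'   user-supplied images already present under `out_dir/images/`.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config, out_dir, simulate = TRUE) {
  config <- as_config(config)
  if (length(config$generator$fold_changes) == 0L) {
    abort("validation: configuration defines zero groups.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(config, out_dir), error = function(e) {
      abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
  }
  if (simulate) stages$simulate <- run_stage("simulate", stage_simulate)
  stages$segment <- run_stage("segment", stage_segment)
  stages$histogram <- run_stage("histogram", stage_histogram)
  stages$compare <- run_stage("compare", stage_compare)

  manifest <- list(
    tool = "opticyto",
    version = as.character(utils::packageVersion("opticyto")),
    seed = config$seed,
    config = strip_classes(config),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
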