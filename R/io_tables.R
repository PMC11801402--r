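#' Write a pipeline table to CSV with a frozen dialect
#'
#' All tabular artifacts (cell tables, event tables, histogram summaries,
#' concordance reports) are written with a fixed dialect — comma separator,
#' '.' decimal mark, '\n' line endings, full double precision — so that a run
#' is reproducible bit-for-bit and a written table rereads identically.
#'
#' @param x A non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  if (nrow(x) == 0L) abort("refusing to write an empty table.")
  readr::write_csv(x, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param col_types Passed to [readr::read_csv()]; defaults to quiet guessing.
#' @export
read_table_csv <- function(path, col_types = readr::cols()) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read flow-cytometry events from CSV
#'
#' Reads list-mode event intensities from a CSV file with a header naming
#' each channel, rescales the requested channel linearly to the 8-bit axis
#' (`value / full_scale * 255`), and returns a tidy event table.
#'
#' @param path CSV file with one row per event and a header row.
#' @param channel_name Column holding the channel of interest.
#' @param full_scale Instrument full-scale value used for the linear rescale
#'   to `[0, 255]`.
#' @param group,source_id Metadata tags attached to every event.
#' @return A tibble with columns `intensity_8bit`, `modality` (`"flow"`),
#'   `group`, `source_id`.
#' @export
read_flow_csv <- function(path, channel_name, full_scale = 255,
                          group = "control", source_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!channel_name %in% names(tbl)) {
    abort(paste0("channel '", channel_name, "' not found in ", path,
                 " (columns: ", paste(names(tbl), collapse = ", "), ")"))
  }
  if (is.null(source_id)) source_id <- basename(path)
  event_table(tbl[[channel_name]] / full_scale * 255,
              modality = "flow", group = group, source_id = source_id)
}

#' Build an event table
#'
#' The flat list-mode container shared by both modalities: one row per cell
#' (imaging) or per event (flow), intensity on the 8-bit `[0, 255]` axis.
#'
#' @param intensity_8bit Numeric vector in `[0, 255]`.
#' @param modality `"imaging"` or `"flow"`.
#' @param group Experimental group label (non-empty).
#' @param source_id Image or tube identifier (recycled).
#' @return A tibble with columns `intensity_8bit`, `modality`, `group`,
#'   `source_id`.
#' @export
event_table <- function(intensity_8bit, modality, group, source_id = "s1") {
  modality <- match.arg(modality, c("imaging", "flow"))
  if (any(!nzchar(group))) abort("`group` must be non-empty.")
  if (anyNA(intensity_8bit) || min(intensity_8bit) < 0 ||
      max(intensity_8bit) > 255) {
    abort("event intensities must lie in [0, 255].")
  }
  tibble(
    intensity_8bit = as.numeric(intensity_8bit),
    modality = modality,
    group = as.character(group),
    source_id = as.character(source_id)
  )
}
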