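# Minimal list-mode FCS 3.0/3.1 support: single data segment, $MODE L,
# $DATATYPE F or I, little- or big-endian per $BYTEORD. Analysis segments,
# compensation and gating metadata are ignored. This is deliberately a small
# subset of the standard — enough to exchange raw event intensities.

fcs_parse_text <- function(txt_raw) {
  delim <- rawToChar(txt_raw[1L])
  body <- rawToChar(txt_raw[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1L]]
  if (length(parts) > 0L && !nzchar(parts[1L])) parts <- parts[-1L]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  setNames(as.list(vals), keys)
}

#' Read flow-cytometry events from an FCS 3.0/3.1 file
#'
#' Parses a list-mode FCS file (single data segment, `$DATATYPE` `F` or `I`,
#' byte order per `$BYTEORD`), extracts one parameter and rescales it
#' linearly to the 8-bit axis: `value / full_scale * 255`.
#'
#' @param path FCS file.
#' @param channel_name `$PnN` short name of the parameter to extract.
#' @param full_scale Full-scale value for the linear rescale; defaults to the
#'   parameter's `$PnR` range keyword.
#' @param group,source_id Metadata tags attached to every event.
#' @return A tibble as from [event_table()], `modality = "flow"`.
#' @export
read_fcs <- function(path, channel_name, full_scale = NULL,
                     group = "control", source_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:6])
  if (!magic %in% c("FCS3.0", "FCS3.1")) {
    abort(paste0("not an FCS 3.0/3.1 file (HEADER magic '", magic, "')"))
  }
  off <- function(i) {
    as.integer(trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)])))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  kw <- fcs_parse_text(raw[(text_beg + 1):(text_end + 1)])
  if (data_beg == 0L || data_end == 0L) {
    data_beg <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "I")) {
    abort(paste0("unsupported $DATATYPE '", dtype, "' (only F and I)"))
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  bits <- as.integer(kw[["$P1B"]])
  endian <- if (grepl("^4", kw[["$BYTEORD"]])) "big" else "little"
  n_bytes <- data_end - data_beg + 1L
  if (n_bytes != n_tot * n_par * (bits / 8L)) {
    abort(sprintf(
      "$TOT (%d) x $PAR (%d) x %d bytes/value does not match the data segment length (%d bytes)",
      n_tot, n_par, bits / 8L, n_bytes))
  }
  con <- rawConnection(raw[(data_beg + 1):(data_end + 1)])
  on.exit(close(con))
  vals <- readBin(con,
                  what = if (dtype == "F") "numeric" else "integer",
                  n = n_tot * n_par, size = bits / 8L, endian = endian,
                  signed = TRUE)
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  names_p <- vapply(seq_len(n_par),
                    function(i) kw[[paste0("$P", i, "N")]], character(1))
  idx <- match(channel_name, names_p)
  if (is.na(idx)) {
    abort(paste0("channel '", channel_name, "' not present (parameters: ",
                 paste(names_p, collapse = ", "), ")"))
  }
  if (is.null(full_scale)) {
    full_scale <- as.numeric(kw[[paste0("$P", idx, "R")]])
  }
  if (is.null(source_id)) source_id <- basename(path)
  event_table(mat[, idx] / full_scale * 255,
              modality = "flow", group = group, source_id = source_id)
}

#' Write a minimal FCS 3.1 list-mode file
#'
#' Emits a standard-conforming single-data-segment FCS 3.1 file. Used to
#' produce synthetic flow samples on disk and as the byte-level round-trip
#' partner of [read_fcs()]; it is not an instrument-grade writer.
#'
#' @param values Numeric matrix (events x parameters) or vector.
#' @param path Output path.
#' @param channel_names `$PnN` names, one per column.
#' @param datatype `"F"` (float32) or `"I"` (int32).
#' @param byteord `"little"` or `"big"`.
#' @param range `$PnR` full-scale range keyword, recycled per parameter.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(values, path, channel_names = NULL, datatype = "F",
                      byteord = "little", range = 262144) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  datatype <- match.arg(datatype, c("F", "I"))
  n_tot <- nrow(values); n_par <- ncol(values)
  if (is.null(channel_names)) channel_names <- paste0("P", seq_len(n_par))
  stopifnot(length(channel_names) == n_par)
  range <- rep_len(range, n_par)
  byteord_kw <- if (byteord == "big") "4,3,2,1" else "1,2,3,4"

  kv <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%010d", "$ENDDATA", "%010d",
    "$BYTEORD", byteord_kw, "$DATATYPE", datatype,
    "$MODE", "L", "$NEXTDATA", "0",
    "$PAR", as.character(n_par), "$TOT", as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kv <- c(kv,
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "N"), channel_names[i],
            paste0("$P", i, "R"), as.character(range[i]))
  }
  text_tpl <- paste0("/", paste(kv, collapse = "/"), "/")
  text_beg <- 58L
  # the two %010d placeholders always expand to 10 characters, so the final
  # text length is known before the offsets are filled in
  text_end <- text_beg + nchar(sprintf(text_tpl, 0L, 0L)) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + n_tot * n_par * 4L - 1L
  text <- sprintf(text_tpl, data_beg, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  flat <- as.vector(t(values))
  if (datatype == "F") {
    writeBin(as.numeric(flat), con, size = 4L, endian = byteord)
  } else {
    writeBin(as.integer(flat), con, size = 4L, endian = byteord)
  }
  invisible(path)
}
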