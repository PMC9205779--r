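# readers/writers for the pipeline's tabular formats
#
# canonical on-disk format is long CSV with an explicit header; TrackMate and
# Imaris spot exports are mapped onto it through a column-alias table.
# conventions stated once and used everywhere: frames are 0-based, t = frame *
# frame_interval (seconds), positions in um, arclength s signed with
# anterograde positive (increasing away from the axon-hillock reference).

#' Column aliases for track tables
#'
#' Maps the canonical column names onto the headers written by common
#' trackers (TrackMate spot tables, Imaris position exports). Extend or
#' override by passing a modified copy to [read_tracks()].
#'
#' @return A named list: canonical name -> character vector of accepted
#'   aliases (case-insensitive).
#' @export
nk_column_aliases <- function() {
  list(
    cell_id  = c("cell_id", "cell", "file", "movie"),
    track_id = c("track_id", "TRACK_ID", "TrackID", "trajectory", "Parent"),
    frame    = c("frame", "FRAME", "Time", "timepoint"),
    t        = c("t", "POSITION_T", "time_s"),
    s        = c("s", "arclength", "position_on_neurite"),
    x        = c("x", "POSITION_X", "Position X"),
    y        = c("y", "POSITION_Y", "Position Y"),
    diameter = c("diameter", "ESTIMATED_DIAMETER", "Diameter", "FIT_DIAMETER")
  )
}

map_aliases <- function(nms, aliases) {
  out <- nms
  lower <- tolower(nms)
  for (canon in names(aliases)) {
    hit <- which(lower %in% tolower(aliases[[canon]]))
    if (length(hit) > 0) out[hit[1]] <- canon
  }
  out
}

#' Read an organelle track table
#'
#' Reads a long-format CSV of organelle trajectories (one row per spot) and
#' validates it: frames must be unique and strictly increasing within each
#' (cell, track), every row needs either a signed arclength `s` or `(x, y)`
#' coordinates in micrometers, and mitochondria tables must carry a
#' `diameter` column. Rows are returned sorted by (cell_id, track_id, frame).
#'
#' @param path CSV file. Headers are matched case-insensitively against
#'   `aliases`.
#' @param schema `"vesicle"` (positions, typically 1-D arclength) or
#'   `"mito"` (positions plus per-frame diameter).
#' @param frame_interval Optional seconds per frame. When given and the file
#'   has no `t` column, `t` is derived as `frame * frame_interval`; when the
#'   file has both, consistency is enforced to 1e-6 s.
#' @param aliases Column-alias table, see [nk_column_aliases()].
#' @return A tibble with columns `cell_id`, `track_id`, `frame`, `t` and the
#'   available position columns.
#' @export
read_tracks <- function(path, schema = c("vesicle", "mito"),
                        frame_interval = NULL,
                        aliases = nk_column_aliases()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- map_aliases(names(raw), aliases)
  validate_tracks(raw, schema = schema, frame_interval = frame_interval,
                  source = path)
}

#' Validate an in-memory track table
#'
#' Applies the same checks as [read_tracks()] to a data frame that is
#' already in memory.
#'
#' @param tracks Data frame with canonical track columns.
#' @inheritParams read_tracks
#' @param source Label used in error messages.
#' @return A validated, sorted tibble.
#' @export
validate_tracks <- function(tracks, schema = c("vesicle", "mito"),
                            frame_interval = NULL, source = "tracks") {
  schema <- match.arg(schema)
  tracks <- tibble::as_tibble(tracks)
  if (!"cell_id" %in% names(tracks)) {
    inform(sprintf("%s: no cell_id column; assuming a single cell 'cell_1'.",
                   source))
    tracks$cell_id <- "cell_1"
  }
  for (col in c("track_id", "frame")) {
    if (!col %in% names(tracks)) {
      abort(sprintf("%s: missing mandatory column `%s`.", source, col))
    }
  }
  has_s <- "s" %in% names(tracks)
  has_xy <- all(c("x", "y") %in% names(tracks))
  if (!has_s && !has_xy) {
    abort(sprintf("%s: needs either column `s` or columns `x` and `y`.",
                  source))
  }
  if (schema == "mito" && !"diameter" %in% names(tracks)) {
    abort(sprintf("%s: mito schema requires a `diameter` column.", source))
  }
  if (any(!is.finite(tracks$frame)) || any(tracks$frame < 0) ||
      any(tracks$frame != round(tracks$frame))) {
    bad <- which(!is.finite(tracks$frame) | tracks$frame < 0 |
                   tracks$frame != round(tracks$frame))
    abort(sprintf("%s: non-integer or negative frame at row(s) %s.",
                  source, paste(head(bad, 5), collapse = ", ")))
  }
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  tracks <- dplyr::arrange(tracks, .data$cell_id, .data$track_id, .data$frame)
  dup <- dplyr::group_by(tracks, .data$cell_id, .data$track_id) |>
    dplyr::filter(duplicated(.data$frame)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    abort(sprintf(
      "%s: duplicated frame within track(s): %s.",
      source, paste(unique(paste(dup$cell_id, dup$track_id, sep = "/")),
                    collapse = ", ")))
  }
  if (!"t" %in% names(tracks)) {
    if (is.null(frame_interval)) {
      abort(sprintf(
        "%s: no `t` column; supply `frame_interval` to derive it.", source))
    }
    tracks$t <- tracks$frame * frame_interval
  } else if (!is.null(frame_interval)) {
    off <- abs(tracks$t - tracks$frame * frame_interval)
    if (any(off > 1e-6)) {
      abort(sprintf(
        "%s: `t` inconsistent with frame * frame_interval (max offset %.3g s).",
        source, max(off)))
    }
  }
  pos_cols <- intersect(c("s", "x", "y"), names(tracks))
  bad_pos <- !Reduce(`|`, lapply(
    list(s = "s", xy = c("x", "y"))[c(has_s, has_xy)],
    function(cols) Reduce(`&`, lapply(cols, function(c) is.finite(tracks[[c]])))
  ))
  if (any(bad_pos)) {
    abort(sprintf("%s: rows without a finite position: %s.",
                  source, paste(head(which(bad_pos), 5), collapse = ", ")))
  }
  dplyr::select(tracks, dplyr::all_of(c("cell_id", "track_id", "frame", "t")),
                dplyr::any_of(c("s", "x", "y", "diameter")),
                dplyr::everything())
}

#' Write a track table (or any pipeline tibble) to CSV
#'
#' Optionally writes a JSON run-metadata sidecar (`<path>.meta.json`)
#' recording the package version, the seed and a config echo, so a result
#' file documents how it was produced.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param meta Optional named list stored as the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, meta = NULL) {
  readr::write_csv(x, path, progress = FALSE)
  if (!is.null(meta)) {
    meta$package <- as.character(utils::packageVersion("neurokinetics"))
    meta$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read FDAP curves
#'
#' Expects columns `cell_id`, `t` (seconds, first retained sample is the
#' first post-activation frame) and `F` (fluorescence). Each cell's curve is
#' renormalized so that its first sample equals 1; the renormalization
#' factors are reported via a message.
#'
#' @param path CSV file with columns `cell_id`, `t`, `F`.
#' @return A tibble (`cell_id`, `t`, `F`) with one curve per cell, each
#'   starting at `F = 1`.
#' @export
read_fdap <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "t", "F")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing mandatory column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  }
  out <- raw |>
    dplyr::mutate(cell_id = as.character(.data$cell_id)) |>
    dplyr::arrange(.data$cell_id, .data$t) |>
    dplyr::group_by(.data$cell_id)
  first_vals <- dplyr::summarise(out, f0 = dplyr::first(.data$F))
  if (any(first_vals$f0 <= 0)) {
    abort(sprintf(
      "Cannot normalize: non-positive first fluorescence in cell(s) %s.",
      paste(first_vals$cell_id[first_vals$f0 <= 0], collapse = ", ")))
  }
  if (any(abs(first_vals$f0 - 1) > 1e-12)) {
    inform(sprintf(
      "Renormalized %d curve(s) so the first sample equals 1.",
      sum(abs(first_vals$f0 - 1) > 1e-12)))
  }
  out <- out |>
    dplyr::mutate(F = .data$F / dplyr::first(.data$F),
                  t = .data$t - dplyr::first(.data$t)) |>
    dplyr::ungroup()
  bad_t <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0) && all(.data$t >= 0))
  if (any(!bad_t$ok)) {
    abort(sprintf("Times must be strictly increasing within cell(s): %s.",
                  paste(bad_t$cell_id[!bad_t$ok], collapse = ", ")))
  }
  out
}

#' Read a single-molecule localization table
#'
#' Expects columns `molecule_id`, `frame`, `x`, `y` (positions in um; frames
#' may contain gaps but must increase strictly within a molecule).
#'
#' @param path CSV file.
#' @return A tibble sorted by (molecule_id, frame).
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("molecule_id", "frame", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing mandatory column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  }
  out <- raw |>
    dplyr::mutate(molecule_id = as.character(.data$molecule_id),
                  frame = as.integer(.data$frame)) |>
    dplyr::arrange(.data$molecule_id, .data$frame)
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    abort(sprintf("%s: non-finite positions present.", path))
  }
  dup <- out |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(dup = anyDuplicated(.data$frame) > 0)
  if (any(dup$dup)) {
    abort(sprintf("%s: duplicated frames within molecule(s) %s.", path,
                  paste(dup$molecule_id[dup$dup], collapse = ", ")))
  }
  out
}
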