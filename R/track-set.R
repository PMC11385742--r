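#' Track sets: tidy multi-animal keypoint trajectories
#'
#' A *track set* is the package's core container: a tibble with one row per
#' (frame, animal, bodypart) holding planar coordinates and a tracking
#' confidence, plus metadata attributes (`fps`, `arena_units`). Frames are
#' 0-based and all animals share the same frame index and bodypart list;
#' missing detections are `NA` coordinates, never dropped rows.
#'
#' @name track_set
NULL

#' Build a track set from a tidy data frame
#'
#' @param x data frame with columns `frame`, `animal`, `bodypart`, `x`, `y`
#'   and optionally `confidence` (defaults to 1 where absent or `NA` only if
#'   the column is missing entirely).
#' @param fps frames per second of the source video (metadata only).
#' @param arena_units free-text label for the coordinate units (e.g. `"px"`
#'   or `"cm"`).
#' @param image_coords if `TRUE`, the y axis is flipped (`y <- -y`) so that
#'   video pixel coordinates (y increasing downwards) obey the package's
#'   mathematical y-up convention. Left/right EWMN side codes (2 = right,
#'   6 = left) are chirality-sensitive, so this flag matters for any pixel
#'   data.
#' @return a `track_set` tibble completed to the full
#'   frame x animal x bodypart grid, ordered by frame, animal, bodypart.
#' @export
as_track_set <- function(x, fps = 30, arena_units = "px", image_coords = FALSE) {
  x <- tibble::as_tibble(x)
  required <- c("frame", "animal", "bodypart", "x", "y")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("track data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$x) || !is.numeric(x$y)) {
    stop("track coordinates `x` and `y` must be numeric", call. = FALSE)
  }
  if (!is.numeric(x$frame)) {
    stop("`frame` must be numeric", call. = FALSE)
  }
  if (!"confidence" %in% names(x)) {
    x$confidence <- 1
  }
  bad_conf <- !is.na(x$confidence) & (x$confidence < 0 | x$confidence > 1)
  if (any(bad_conf)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(x[c("frame", "animal", "bodypart")]) > 0) {
    stop("duplicated (frame, animal, bodypart) rows in track data",
         call. = FALSE)
  }
  if (image_coords) x$y <- -x$y
  x$frame <- as.integer(x$frame)
  x$animal <- as.character(x$animal)
  x$bodypart <- as.character(x$bodypart)
  # complete the grid so every animal shares the same frame/bodypart index
  all_frames <- tidyr::full_seq(c(0L, x$frame), 1L)
  out <- tidyr::complete(
    x,
    frame = all_frames,
    .data$animal, .data$bodypart
  )
  out <- dplyr::arrange(out, .data$frame, .data$animal, .data$bodypart)
  out <- dplyr::select(out, "frame", "animal", "bodypart", "x", "y",
                       "confidence")
  new_track_set(out, fps = fps, arena_units = arena_units)
}

new_track_set <- function(df, fps, arena_units) {
  structure(df,
            fps = fps,
            arena_units = arena_units,
            class = c("track_set", class(tibble::tibble())))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d frames, %d animals (%s), %d bodyparts, %g fps, units: %s\n",
              n_frames(x), length(animals(x)),
              paste(animals(x), collapse = ", "),
              length(bodyparts(x)), attr(x, "fps"), attr(x, "arena_units")))
  NextMethod()
}

#' Track-set accessors
#'
#' @param ts a `track_set`.
#' @return `animals()` and `bodyparts()` return character vectors in their
#'   canonical (sorted) order; `n_frames()` the number of frames `T` (frames
#'   are indexed `0:(T-1)`).
#' @export
animals <- function(ts) sort(unique(ts$animal))

#' @rdname animals
#' @export
bodyparts <- function(ts) sort(unique(ts$bodypart))

#' @rdname animals
#' @export
n_frames <- function(ts) max(ts$frame) + 1L

# Internal: coordinates of one animal as an array [frame, bodypart, 2],
# rows indexed by frame 0..T-1 in order, bodyparts in `parts` order.
track_array <- function(ts, animal, parts) {
  sub <- ts[ts$animal == animal & ts$bodypart %in% parts, ]
  t_n <- n_frames(ts)
  arr <- array(NA_real_, dim = c(t_n, length(parts), 2),
               dimnames = list(NULL, parts, c("x", "y")))
  fi <- sub$frame + 1L
  pi <- match(sub$bodypart, parts)
  arr[cbind(fi, pi, 1L)] <- sub$x
  arr[cbind(fi, pi, 2L)] <- sub$y
  arr
}

#' Write a track set as a tidy long CSV
#'
#' The output has columns `frame, animal, bodypart, x, y, confidence` and
#' can be read back with [read_tidy_tracks()]; coordinates round-trip
#' exactly for non-missing points.
#'
#' @param ts a `track_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tidy_tracks <- function(ts, path) {
  df <- tibble::as_tibble(ts)
  # full 17-significant-digit output so coordinates round-trip bit-exactly
  num_fmt <- function(v) ifelse(is.na(v), NA_character_,
                                sprintf("%.17g", v))
  df$x <- num_fmt(df$x)
  df$y <- num_fmt(df$y)
  df$confidence <- num_fmt(df$confidence)
  readr::write_csv(df, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read tidy long-format tracks
#'
#' Reads a long-format CSV with columns `frame, animal, bodypart, x, y` and
#' an optional `confidence` column (assumed 1.0 where absent). Missing
#' (frame, animal, bodypart) combinations become missing points.
#'
#' @inheritParams as_track_set
#' @param path CSV file path.
#' @return a `track_set`.
#' @export
read_tidy_tracks <- function(path, fps = 30, arena_units = "px",
                             image_coords = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default =
                                                  readr::col_character()))
  required <- c("frame", "animal", "bodypart", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("tidy track file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # base-R numeric conversion: correctly rounded, so coordinates written
  # at full precision round-trip bit-exactly
  to_num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & nzchar(v) & is.na(out))) {
      stop("non-numeric ", what, " in tidy track file", call. = FALSE)
    }
    out
  }
  df$frame <- to_num(df$frame, "frame values")
  df$x <- to_num(df$x, "coordinates")
  df$y <- to_num(df$y, "coordinates")
  if ("confidence" %in% names(df)) {
    df$confidence <- to_num(df$confidence, "confidence values")
  }
  as_track_set(df, fps = fps, arena_units = arena_units,
               image_coords = image_coords)
}
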