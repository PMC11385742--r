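#' Clean keypoint trajectories
#'
#' Three-stage, per-(animal, bodypart) cleaning: (1) points with
#' `confidence < min_confidence` are set missing; (2) interior missing runs
#' of length `<= max_gap` are linearly interpolated per coordinate;
#' (3) each coordinate is smoothed with a centred moving median of width
#' `smooth_window` (robust to tracking identity flips). Leading and
#' trailing missing runs are never filled. Cleaning is total: it never
#' errors, never changes the frame count, animal list or bodypart list,
#' and with `min_confidence = 0`, `max_gap = 0`, `smooth_window = 1` it is
#' the identity. All three stages default to "off".
#'
#' @param ts a `track_set`.
#' @param min_confidence points below this confidence are treated as
#'   missing (default 0: keep everything).
#' @param max_gap longest interior missing run (frames) to interpolate
#'   (default 0: no interpolation).
#' @param smooth_window odd moving-median width in frames (default 1: no
#'   smoothing).
#' @return a cleaned `track_set` with a `cleaning_report` attribute: a
#'   tibble of per-(animal, bodypart) counts of dropped, interpolated and
#'   still-missing frames.
#' @export
clean_tracks <- function(ts, min_confidence = 0, max_gap = 0,
                         smooth_window = 1) {
  stopifnot(max_gap >= 0, smooth_window >= 1, smooth_window %% 2 == 1)
  df <- tibble::as_tibble(ts)
  df <- dplyr::arrange(df, .data$animal, .data$bodypart, .data$frame)

  cleaned <- df |>
    dplyr::group_by(.data$animal, .data$bodypart) |>
    dplyr::group_modify(function(g, key) {
      clean_one(g, min_confidence, max_gap, smooth_window)
    }) |>
    dplyr::ungroup()

  report <- cleaned |>
    dplyr::group_by(.data$animal, .data$bodypart) |>
    dplyr::summarise(
      dropped = sum(.data$.dropped),
      interpolated = sum(.data$.interp),
      missing = sum(is.na(.data$x)),
      all_missing = all(is.na(.data$x)),
      .groups = "drop"
    )
  if (any(report$all_missing)) {
    bad <- report[report$all_missing, ]
    warning("all frames missing after cleaning for: ",
            paste(bad$animal, bad$bodypart, sep = "/", collapse = ", "),
            call. = FALSE)
  }

  out <- dplyr::select(cleaned, "frame", "animal", "bodypart", "x", "y",
                       "confidence")
  out <- dplyr::arrange(out, .data$frame, .data$animal, .data$bodypart)
  out <- new_track_set(out, fps = attr(ts, "fps"),
                       arena_units = attr(ts, "arena_units"))
  attr(out, "cleaning_report") <- report
  out
}

clean_one <- function(g, min_confidence, max_gap, smooth_window) {
  x <- g$x
  y <- g$y
  drop <- !is.na(g$confidence) & g$confidence < min_confidence &
    !is.na(x)
  x[drop] <- NA_real_
  y[drop] <- NA_real_

  interp <- rep(FALSE, length(x))
  if (max_gap > 0) {
    fill <- interior_gaps(is.na(x) | is.na(y), max_gap)
    if (any(fill)) {
      x <- fill_linear(x, fill)
      y <- fill_linear(y, fill)
      interp <- fill
    }
  }

  if (smooth_window > 1) {
    x <- roll_median(x, smooth_window)
    y <- roll_median(y, smooth_window)
  }

  tibble::tibble(frame = g$frame, x = x, y = y,
                 confidence = g$confidence,
                 .dropped = drop, .interp = interp)
}

# logical vector marking interior NA runs of length <= max_gap
interior_gaps <- function(na, max_gap) {
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep(FALSE, length(na))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] <= max_gap &&
        starts[i] > 1L && ends[i] < length(na)) {
      out[starts[i]:ends[i]] <- TRUE
    }
  }
  out
}

# linear interpolation restricted to the marked positions
fill_linear <- function(v, fill) {
  idx <- which(!is.na(v))
  if (length(idx) < 2) return(v)
  interp <- stats::approx(idx, v[idx], xout = which(fill))$y
  v[fill] <- interp
  v
}

# centred moving median, NA-tolerant, ends use the available window
roll_median <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  was_na <- is.na(v)
  out <- vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
  out[was_na] <- NA_real_   # smoothing never invents points
  out
}
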