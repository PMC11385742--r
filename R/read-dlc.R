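#' Read DeepLabCut keypoint trajectories
#'
#' Parses the CSV dialects written by DeepLabCut pose estimation.
#' Multi-animal files carry four header rows (`scorer`, `individuals`,
#' `bodyparts`, `coords`); single-animal files three (`scorer`,
#' `bodyparts`, `coords`). Each bodypart contributes `x`, `y` and
#' `likelihood` columns; `likelihood` is mapped directly onto the track
#' set's `confidence`. Rows map to frames by order (frame 0 first); a
#' leading index column, if present, is ignored for indexing.
#'
#' An HDF5 dialect identifier is accepted for forward compatibility but is
#' not currently readable: no HDF5 interface is available to this package,
#' so requesting it raises a format error suggesting CSV export.
#'
#' @param path file path.
#' @param dialect one of `"multi_animal_csv"`, `"single_animal_csv"`,
#'   `"hdf5"`.
#' @inheritParams as_track_set
#' @param animal animal identifier to assign for single-animal files.
#' @return a `track_set`.
#' @export
read_dlc_tracks <- function(path,
                            dialect = c("multi_animal_csv",
                                        "single_animal_csv", "hdf5"),
                            fps = 30, arena_units = "px",
                            image_coords = TRUE, animal = "animal1") {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    stop("format error: the DLC HDF5 dialect is not readable here; ",
         "export the tracks to CSV and use dialect = \"multi_animal_csv\" ",
         "or \"single_animal_csv\"", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  n_header <- if (dialect == "multi_animal_csv") 4L else 3L
  header_names <- if (n_header == 4L) {
    c("scorer", "individuals", "bodyparts", "coords")
  } else {
    c("scorer", "bodyparts", "coords")
  }

  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) < n_header) {
    stop("format error: expected ", n_header, " header rows (",
         paste(header_names, collapse = ", "), "), file has ", nrow(raw),
         " rows", call. = FALSE)
  }
  hdr <- as.matrix(raw[seq_len(n_header), ])
  first_col_label <- hdr[, 1]
  got <- tolower(trimws(first_col_label))
  for (i in seq_len(n_header)) {
    if (!identical(got[i], header_names[i])) {
      stop("format error: missing or misplaced `", header_names[i],
           "` header row (row ", i, " is labelled `", first_col_label[i],
           "`)", call. = FALSE)
    }
  }

  data_cols <- 2:ncol(raw)
  coords <- tolower(hdr[n_header, data_cols])
  parts <- hdr[n_header - 1L, data_cols]
  indiv <- if (n_header == 4L) hdr[2, data_cols] else rep(animal,
                                                          length(data_cols))
  keep <- coords %in% c("x", "y", "likelihood")
  if (!any(keep)) {
    stop("format error: no x/y/likelihood coordinate columns found",
         call. = FALSE)
  }

  combos <- paste(indiv[keep], parts[keep], coords[keep], sep = "\r")
  if (anyDuplicated(combos) > 0) {
    dup <- combos[duplicated(combos)][1]
    dup <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stop("validation error: duplicated (individual, bodypart) column: ",
         dup[1], "/", dup[2], call. = FALSE)
  }

  body <- raw[-seq_len(n_header), , drop = FALSE]
  if (nrow(body) == 0) {
    stop("validation error: no data rows after the header", call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(body[, data_cols, drop = FALSE])),
           nrow = nrow(body))
  )
  n_t <- nrow(body)

  long <- tibble::tibble(
    frame = rep(seq_len(n_t) - 1L, times = sum(keep)),
    animal = rep(indiv[keep], each = n_t),
    bodypart = rep(parts[keep], each = n_t),
    coord = rep(coords[keep], each = n_t),
    value = as.vector(vals[, keep, drop = FALSE])
  )
  wide <- tidyr::pivot_wider(long, names_from = "coord",
                             values_from = "value")
  if (!"likelihood" %in% names(wide)) wide$likelihood <- 1
  wide$likelihood[is.na(wide$likelihood)] <- 1
  wide <- dplyr::rename(wide, confidence = "likelihood")
  as_track_set(wide, fps = fps, arena_units = arena_units,
               image_coords = image_coords)
}
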