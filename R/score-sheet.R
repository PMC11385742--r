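#' Notation-style score sheets
#'
#' A score sheet condenses a dyad series into the classic notated-page
#' layout: one row per notation line — `Front(a)`, `Weight(a)`, the three
#' inter-animal measures, `Weight(b)`, `Front(b)` — with time running left
#' to right in columns of every `stride`-th frame. Codes are run-length
#' compressed: a cell appears only where the code changes (the first
#' sampled frame always appears). Distance is quantised to 0.25
#' body-length increments before compression.
#'
#' @param ds a `dyad_series` from [relational_series()].
#' @param stride sampling stride in frames (default 1).
#' @return a `score_sheet`: tibble with columns `row` (notation line,
#'   ordered factor), `frame`, `value` (character code), holding only
#'   change points.
#' @export
export_score_sheet <- function(ds, stride = 1) {
  ans <- sort(unique(ds$kinematics$animal))
  m <- ds$measures[ds$measures$focal == ans[1], ]
  ka <- ds$kinematics[ds$kinematics$animal == ans[1], ]
  kb <- ds$kinematics[ds$kinematics$animal == ans[2], ]
  frames <- seq(0, max(m$frame), by = stride)
  sel <- function(v, fr) v[match(frames, fr)]
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  dist_q <- fmt(round(sel(m$rel_distance, m$frame) / 0.25) * 0.25)
  rows <- list(
    "Front(a)" = fmt(sel(ka$front, ka$frame)),
    "Weight(a)" = fmt(sel(ka$weight_code, ka$frame)),
    "partnerwise" = fmt(sel(m$partnerwise, m$frame)),
    "opposition" = fmt(sel(m$opposition, m$frame)),
    "distance" = dist_q,
    "Weight(b)" = fmt(sel(kb$weight_code, kb$frame)),
    "Front(b)" = fmt(sel(kb$front, kb$frame))
  )
  out <- purrr::imap(rows, function(v, nm) {
    change <- c(TRUE, v[-1] != v[-length(v)])
    tibble::tibble(row = nm, frame = frames[change], value = v[change])
  })
  out <- dplyr::bind_rows(out)
  out$row <- factor(out$row, levels = names(rows))
  class(out) <- c("score_sheet", class(out))
  attr(out, "stride") <- stride
  out
}

#' Write a score sheet as UTF-8 text
#'
#' One line per notation row, cells as `code@frame` change points, e.g.
#' `partnerwise: 4@0 6@153`.
#'
#' @param sheet a `score_sheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_sheet <- function(sheet, path) {
  lines <- vapply(levels(sheet$row), function(r) {
    s <- sheet[sheet$row == r, ]
    paste0(r, ": ", paste0(s$value, "@", s$frame, collapse = " "))
  }, character(1))
  writeLines(c(sprintf("# score sheet (stride %d)", attr(sheet, "stride")),
               lines), path, useBytes = TRUE)
  invisible(path)
}

#' Parse a written score sheet back into its change points
#'
#' @param path file written by [write_score_sheet()].
#' @return a tibble with columns `row`, `frame`, `value`.
#' @export
parse_score_sheet <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    parts <- strsplit(l, ": ", fixed = TRUE)[[1]]
    cells <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    at <- regmatches(cells, regexpr("@[0-9]+$", cells))
    tibble::tibble(
      row = parts[1],
      frame = as.integer(sub("@", "", at)),
      value = substr(cells, 1, nchar(cells) - nchar(at))
    )
  })
}
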