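#' Body models: mapping anatomy onto EWMN surface codes
#'
#' A body model describes how an animal's tracked keypoints form its
#' longitudinal axis and how positions along that axis map onto named body
#' regions and contact segments.
#'
#' * `midline`: ordered bodypart names, anterior to posterior (at least 2).
#' * `region_bounds`: named numeric vector of strictly increasing arc-
#'   fraction upper bounds partitioning `[0, 1]` into labelled regions.
#'   The default `c(H = 0.25, S = 0.5, T = 1)` splits the axis into head,
#'   shoulder and torso; these fractions are a convention, not a species
#'   fact, and should be set per species.
#' * `tip_fraction`: arc fraction at either end treated as the front/rear
#'   tip (surface codes 0 and 4), default 0.05.
#' * `heading`: length-2 character vector `(base, tip)` naming the
#'   bodyparts whose base-to-tip vector is the facing direction; defaults
#'   to the posterior-most and anterior-most midline points.
#' * `n_segments`: number of equal arc-length contact segments (default 4,
#'   segment 1 = head end).
#'
#' @param midline ordered bodypart names, anterior first.
#' @param region_bounds named numeric vector of arc-fraction upper bounds.
#' @param tip_fraction tip arc fraction, in (0, 0.5).
#' @param heading optional `(base, tip)` bodypart pair.
#' @param n_segments number of contact segments.
#' @return a `body_model` object.
#' @examples
#' bm <- body_model(c("head", "pronotum", "mid_abdomen", "abdomen_tip"))
#' @export
body_model <- function(midline,
                       region_bounds = c(H = 0.25, S = 0.5, T = 1),
                       tip_fraction = 0.05,
                       heading = NULL,
                       n_segments = 4) {
  midline <- as.character(midline)
  if (length(midline) < 2 || anyDuplicated(midline) > 0) {
    stop("`midline` needs at least 2 unique bodypart names", call. = FALSE)
  }
  if (is.null(names(region_bounds)) || any(names(region_bounds) == "")) {
    stop("`region_bounds` must be a named vector of arc-fraction bounds",
         call. = FALSE)
  }
  if (any(diff(region_bounds) <= 0) ||
      abs(region_bounds[length(region_bounds)] - 1) > 1e-12 ||
      any(region_bounds <= 0)) {
    stop("`region_bounds` must be strictly increasing in (0, 1] ending at 1",
         call. = FALSE)
  }
  if (tip_fraction <= 0 || tip_fraction >= 0.5) {
    stop("`tip_fraction` must lie in (0, 0.5)", call. = FALSE)
  }
  if (is.null(heading)) {
    heading <- c(base = midline[length(midline)], tip = midline[1])
  } else {
    heading <- stats::setNames(as.character(heading), c("base", "tip"))
  }
  structure(
    list(midline = midline, region_bounds = region_bounds,
         tip_fraction = tip_fraction, heading = heading,
         n_segments = as.integer(n_segments)),
    class = "body_model"
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model>\n")
  cat("  midline:  ", paste(x$midline, collapse = " -> "), "\n")
  cat("  regions:  ", paste(names(x$region_bounds), x$region_bounds,
                            sep = "<=", collapse = ", "), "\n")
  cat("  tips:     ", x$tip_fraction, "of arc length\n")
  cat("  heading:  ", x$heading[["base"]], "->", x$heading[["tip"]], "\n")
  cat("  segments: ", x$n_segments, "\n")
  invisible(x)
}

#' Read a body model from a YAML config
#'
#' Schema (all keys except `midline` optional):
#' ```yaml
#' midline: [head, pronotum, mid_abdomen, abdomen_tip]
#' region_bounds: {H: 0.25, S: 0.5, T: 1.0}
#' tip_fraction: 0.05
#' heading: {base: abdomen_tip, tip: head}
#' n_segments: 4
#' ```
#'
#' @param path YAML file path.
#' @return a `body_model`.
#' @export
read_body_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$midline)) {
    stop("body model config must define `midline`", call. = FALSE)
  }
  rb <- if (is.null(y$region_bounds)) c(H = 0.25, S = 0.5, T = 1) else
    unlist(y$region_bounds)
  hd <- if (is.null(y$heading)) NULL else c(y$heading$base, y$heading$tip)
  body_model(
    midline = unlist(y$midline),
    region_bounds = rb,
    tip_fraction = y$tip_fraction %||% 0.05,
    heading = hd,
    n_segments = y$n_segments %||% 4
  )
}

#' Write a body model to YAML
#' @param bm a `body_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_body_model <- function(bm, path) {
  yaml::write_yaml(list(
    midline = bm$midline,
    region_bounds = as.list(bm$region_bounds),
    tip_fraction = bm$tip_fraction,
    heading = list(base = unname(bm$heading[["base"]]),
                   tip = unname(bm$heading[["tip"]])),
    n_segments = bm$n_segments
  ), path)
  invisible(path)
}
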