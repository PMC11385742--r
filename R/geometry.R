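#' Per-animal body geometry
#'
#' The longitudinal axis of an animal is realised as a polyline through its
#' midline keypoints in anatomical (anterior to posterior) order. All
#' body-surface and opposition measures are computed against this polyline;
#' body width/outline is unmodelled because only midline keypoints are
#' observed.
#'
#' @name body_geometry
NULL

#' Midline polyline for one frame
#'
#' @param pose a frame's keypoints: matrix/data frame with rownames (or a
#'   `bodypart` column) naming bodyparts and columns `x`, `y`.
#' @param bm a [body_model()].
#' @return a `midline_polyline`: list with `vertices` (n x 2 matrix,
#'   anterior first), `cum` (cumulative arc length from the anterior tip),
#'   and `length` (total arc length in arena units) — or `NULL` (the
#'   undefined-frame marker) when fewer than 2 distinct midline points are
#'   present this frame. Missing interior points are skipped.
#' @export
midline_polyline <- function(pose, bm) {
  m <- pose_matrix(pose)
  present <- intersect(bm$midline, rownames(m))
  v <- m[present, , drop = FALSE]
  ok <- stats::complete.cases(v)
  v <- v[ok, , drop = FALSE]
  if (nrow(v) >= 2) {
    # drop consecutive duplicated vertices (zero-length segments)
    keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) < 2) return(NULL)
  seg <- unname(sqrt(rowSums(diff(v)^2)))
  cum <- c(0, cumsum(seg))
  list(vertices = unname(v), cum = cum, length = cum[length(cum)])
}

pose_matrix <- function(pose) {
  if (is.data.frame(pose)) {
    m <- as.matrix(pose[, c("x", "y")])
    rownames(m) <- pose$bodypart
    m
  } else {
    pose[, c("x", "y"), drop = FALSE]
  }
}

#' Heading angle of a pose
#'
#' The facing direction is the base-to-tip vector named by the body
#' model's `heading` pair, expressed in degrees clockwise from the arena
#' reference direction (+y). A pose facing up-page has heading 0; facing
#' right-page, 90.
#'
#' @inheritParams midline_polyline
#' @return heading in degrees `[0, 360)`, or `NA` when either heading
#'   bodypart is missing or the heading vector has zero length.
#' @export
heading_angle <- function(pose, bm) {
  m <- pose_matrix(pose)
  b <- bm$heading[["base"]]
  t <- bm$heading[["tip"]]
  if (!all(c(b, t) %in% rownames(m))) return(NA_real_)
  d <- m[t, ] - m[b, ]
  if (any(is.na(d)) || all(d == 0)) return(NA_real_)
  unname(bearing_cw(d[1], d[2]))
}

#' Reference body length of an animal
#'
#' The animal-lengths unit used for relative distance: the median of the
#' per-frame total midline arc length over all frames where the midline is
#' defined. The median makes the estimate robust to flexion and tracking
#' glitches, recovering the relaxed snout-to-tail-base length.
#'
#' @param ts a `track_set`.
#' @param animal animal identifier.
#' @param bm a [body_model()].
#' @return reference length in arena units.
#' @export
reference_length <- function(ts, animal, bm) {
  arr <- track_array(ts, animal, bm$midline)
  lens <- vapply(seq_len(dim(arr)[1]), function(i) {
    p <- frame_pose(arr, i)
    poly <- midline_polyline(p, bm)
    if (is.null(poly)) NA_real_ else poly$length
  }, numeric(1))
  if (all(is.na(lens))) {
    stop("no frame with a defined midline for animal ", animal,
         call. = FALSE)
  }
  stats::median(lens, na.rm = TRUE)
}

frame_pose <- function(arr, i) {
  m <- arr[i, , , drop = FALSE]
  dim(m) <- dim(arr)[2:3]
  rownames(m) <- dimnames(arr)[[2]]
  colnames(m) <- c("x", "y")
  m
}

# Closest point on segment [a, b] to point p. Returns c(x, y, t, d2).
closest_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else
    min(1, max(0, sum((p - a) * ab) / len2))
  q <- a + t * ab
  c(q, t, sum((p - q)^2))
}

# Closest point on a polyline to p.
# Ties between segments break toward the more anterior segment.
# Returns list(point, arc, dist, seg).
closest_on_polyline <- function(poly, p) {
  v <- poly$vertices
  n <- nrow(v) - 1L
  best <- NULL
  for (i in seq_len(n)) {
    r <- closest_on_segment(p, v[i, ], v[i + 1L, ])
    if (is.null(best) || r[4] < best$d2 - 1e-12 * max(1, best$d2)) {
      best <- list(point = r[1:2], t = r[3], d2 = r[4], seg = i)
    }
  }
  arc <- poly$cum[best$seg] +
    best$t * (poly$cum[best$seg + 1L] - poly$cum[best$seg])
  list(point = best$point, arc = arc, dist = sqrt(best$d2), seg = best$seg)
}

#' Body-surface (opposition) coordinate of an external point
#'
#' Wraps the EWMN horizontal ring around the animal's body: the returned
#' code is 0 at the front tip, 4 at the rear tip, 2 on the right side and
#' 6 on the left, with side codes carrying the body-region letter (e.g.
#' `"2H"` = right side of the head). The nearest point on the midline
#' polyline determines the arc position; the sign of the 2-D cross product
#' of the local facing direction with the offset vector determines the
#' side. Tip codes (0/4) require both an arc position within
#' `tip_fraction` of the relevant end and the point lying within a 45
#' degree cone around the axis extension, since a point alongside the head
#' is a side-of-head opposition, not a frontal one.
#'
#' @param poly a `midline_polyline`.
#' @param point numeric `(x, y)`.
#' @param bm a [body_model()].
#' @return a one-row tibble: `code` (0, 2, 4 or 6), `region` (region label
#'   for side codes, `NA` for tips), `arc_fraction`, `side`
#'   (`"right"`, `"left"`, `"on-axis"`), `label` (e.g. `"2H"`, `"0"`),
#'   `segment` (contact segment 1..`n_segments`, 1 = head end), `dist`
#'   (arena units to the nearest midline point).
#' @export
surface_coordinate <- function(poly, point, bm) {
  s <- surface_core(poly, point, bm)
  tibble::tibble(code = s$code, region = s$region,
                 arc_fraction = s$arc_fraction, side = s$side,
                 label = s$label, segment = s$segment, dist = s$dist)
}

# list-returning core of surface_coordinate (hot path)
surface_core <- function(poly, point, bm) {
  stopifnot(!is.null(poly))
  cp <- closest_on_polyline(poly, point)
  af <- if (poly$length > 0) cp$arc / poly$length else 0
  v <- poly$vertices
  n <- nrow(v)

  d <- point - cp$point
  seg_dir <- v[cp$seg + 1L, ] - v[cp$seg, ]          # anterior -> posterior
  facing <- -seg_dir / sqrt(sum(seg_dir^2))           # local facing (unit)
  crossz <- facing[1] * d[2] - facing[2] * d[1]
  nd <- sqrt(sum(d^2))
  eps <- 1e-9 * max(1, poly$length)
  side <- if (nd <= eps || abs(crossz) <= eps * nd) "on-axis"
          else if (crossz < 0) "right" else "left"

  code <- NA_integer_
  if (af <= bm$tip_fraction) {
    u <- v[1, ] - v[2, ]                              # anterior extension
    if (in_cone(point - v[1, ], u, nd, eps)) code <- 0L
  }
  if (is.na(code) && af >= 1 - bm$tip_fraction) {
    u <- v[n, ] - v[n - 1L, ]                         # posterior extension
    if (in_cone(point - v[n, ], u, nd, eps)) code <- 4L
  }
  if (is.na(code)) {
    code <- switch(side,
                   right = 2L, left = 6L,
                   `on-axis` = if (af < 0.5) 0L else 4L)
  }
  region <- if (code %in% c(2L, 6L)) region_of(af, bm) else NA_character_
  label <- if (is.na(region)) as.character(code) else
    paste0(code, region)
  list(code = code, region = region, arc_fraction = af, side = side,
       label = label, segment = segment_of(af, bm$n_segments),
       dist = cp$dist)
}

# is vector w within 45 degrees of direction u (or degenerate/at the tip)?
in_cone <- function(w, u, nd, eps) {
  nw <- sqrt(sum(w^2))
  nu <- sqrt(sum(u^2))
  if (nw <= eps || nu <= eps) return(TRUE)   # at the tip itself
  cosang <- sum(w * u) / (nw * nu)
  cosang >= cos(pi / 4) - 1e-12
}

region_of <- function(af, bm) {
  names(bm$region_bounds)[which(af <= bm$region_bounds + 1e-12)[1]]
}

segment_of <- function(af, n_segments) {
  pmin(n_segments, as.integer(floor(af * n_segments)) + 1L)
}

# Exact closest pair of points between two polylines
# (segment-to-segment minimisation; for non-crossing segments the minimum
# is attained at an endpoint of one of them, so four point-segment
# projections plus a crossing test are exhaustive).
# Returns list(p (on poly1), q (on poly2), gap).
closest_pair_polylines <- function(poly1, poly2) {
  v1 <- poly1$vertices
  v2 <- poly2$vertices
  best <- list(p = NULL, q = NULL, d2 = Inf)
  for (i in seq_len(nrow(v1) - 1L)) {
    a <- v1[i, ]; b <- v1[i + 1L, ]
    for (j in seq_len(nrow(v2) - 1L)) {
      c2 <- v2[j, ]; d2 <- v2[j + 1L, ]
      if (segments_cross(a, b, c2, d2)) {
        x <- segment_intersection(a, b, c2, d2)
        return(list(p = x, q = x, gap = 0))
      }
      cand <- list(
        {r <- closest_on_segment(a, c2, d2); list(p = a, q = r[1:2], d2 = r[4])},
        {r <- closest_on_segment(b, c2, d2); list(p = b, q = r[1:2], d2 = r[4])},
        {r <- closest_on_segment(c2, a, b); list(p = r[1:2], q = c2, d2 = r[4])},
        {r <- closest_on_segment(d2, a, b); list(p = r[1:2], q = d2, d2 = r[4])}
      )
      for (k in cand) if (k$d2 < best$d2) best <- k
    }
  }
  list(p = best$p, q = best$q, gap = sqrt(best$d2))
}

segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                                (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

segment_intersection <- function(a, b, c, d) {
  r <- b - a; s <- d - c
  denom <- r[1] * s[2] - r[2] * s[1]
  t <- ((c[1] - a[1]) * s[2] - (c[2] - a[2]) * s[1]) / denom
  a + t * r
}
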