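# Shared builders and independent brute-force oracles.

# tidy rows for one rigid pose: centroid `cent`, heading `theta` (deg,
# clockwise from +y), body length L, K keypoints head-first
rigid_pose_rows <- function(frame, animal, cent, theta, L = 10, K = 4,
                            parts = c("head", "pronotum", "mid_abdomen",
                                      "abdomen_tip")) {
  r <- theta * pi / 180
  u <- c(sin(r), cos(r))
  offs <- L / 2 - (seq_len(K) - 1) * L / (K - 1)
  data.frame(frame = frame, animal = animal, bodypart = parts[seq_len(K)],
             x = cent[1] + offs * u[1], y = cent[2] + offs * u[2],
             confidence = 1)
}

# track set of two rigid animals given per-frame centroids and headings
rigid_dyad_tracks <- function(cent_a, th_a, cent_b, th_b, L = 10, K = 4) {
  t_n <- length(th_a)
  rows <- lapply(seq_len(t_n), function(i) {
    rbind(rigid_pose_rows(i - 1L, "a", cent_a[i, ], th_a[i], L, K),
          rigid_pose_rows(i - 1L, "b", cent_b[i, ], th_b[i], L, K))
  })
  as_track_set(do.call(rbind, rows))
}

default_bm <- function() {
  body_model(c("head", "pronotum", "mid_abdomen", "abdomen_tip"))
}

# random open polyline as a smooth-ish walk, scaled to unit-order size
random_polyline_pts <- function(k = 4, scale = 1) {
  ang <- runif(1, 0, 2 * pi) + cumsum(c(0, runif(k - 2, -0.8, 0.8)))
  steps <- runif(k - 1, 0.5, 1.5) * scale
  x <- cumsum(c(runif(1, -2, 2), steps * cos(ang)))
  y <- cumsum(c(runif(1, -2, 2), steps * sin(ang)))
  cbind(x, y)
}

poly_from_pts <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  list(vertices = unname(pts), cum = c(0, cumsum(seg)),
       length = sum(seg))
}

# dense sampling of a polyline at n points, with arc positions
dense_sample <- function(poly, n = 2000) {
  arcs <- seq(0, poly$length, length.out = n)
  seg_idx <- findInterval(arcs, poly$cum, rightmost.closed = TRUE)
  seg_idx <- pmin(seg_idx, nrow(poly$vertices) - 1L)
  t0 <- poly$cum[seg_idx]
  t1 <- poly$cum[seg_idx + 1L]
  w <- ifelse(t1 > t0, (arcs - t0) / (t1 - t0), 0)
  pts <- poly$vertices[seg_idx, , drop = FALSE] * (1 - w) +
    poly$vertices[seg_idx + 1L, , drop = FALSE] * w
  list(pts = pts, arcs = arcs)
}

# brute-force nearest point on polyline by dense sampling
brute_nearest <- function(poly, p, n = 10000) {
  s <- dense_sample(poly, n)
  d2 <- (s$pts[, 1] - p[1])^2 + (s$pts[, 2] - p[2])^2
  i <- which.min(d2)
  list(arc = s$arcs[i], dist = sqrt(d2[i]),
       arc_fraction = s$arcs[i] / poly$length,
       spacing = poly$length / (n - 1))
}

# brute-force closest pair between two polylines by dense sampling
brute_closest_pair <- function(poly1, poly2, n = 400) {
  s1 <- dense_sample(poly1, n)$pts
  s2 <- dense_sample(poly2, n)$pts
  d2 <- outer(s1[, 1], s2[, 1], "-")^2 + outer(s1[, 2], s2[, 2], "-")^2
  sqrt(min(d2))
}

# rigid motion + scaling applied to a track set
transform_tracks <- function(ts, angle = 0, shift = c(0, 0), scale = 1,
                             mirror_x = FALSE) {
  df <- tibble::as_tibble(ts)
  r <- angle * pi / 180
  x <- df$x * cos(r) - df$y * sin(r)
  y <- df$x * sin(r) + df$y * cos(r)
  df$x <- scale * x + shift[1]
  df$y <- scale * y + shift[2]
  if (mirror_x) df$x <- -df$x
  as_track_set(df, fps = attr(ts, "fps"),
               arena_units = attr(ts, "arena_units"))
}
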