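#' Joints: invariant-configuration intervals and their maintenance
#'
#' When an inter-animal measure stays constant over an extended run of
#' frames while one or both animals keep moving, the configuration acts
#' like a virtual "joint" between the interactants — an attractor that the
#' animals' movements maintain. This module detects such intervals,
#' quantifies how compensatory the animals' motion is within them, and
#' attributes configurational *changes* to the animal(s) that produced
#' them via counterfactual pose freezing.
#'
#' @name joints
NULL

# character code series for one measure, focal-first pair; NA = undefined
code_series <- function(ds, measure = c("partnerwise", "opposition",
                                        "combined"), focal = NULL) {
  measure <- match.arg(measure)
  ans <- sort(unique(ds$measures$focal))
  focal <- focal %||% ans[1]
  m <- ds$measures[ds$measures$focal == focal, ]
  m <- m[order(m$frame), ]
  v <- switch(measure,
              partnerwise = as.character(m$partnerwise),
              opposition = m$opposition,
              combined = paste0(m$partnerwise, "|", m$opposition))
  v[!m$defined] <- NA_character_
  v
}

# centred mode filter of odd width k on a character series (NA ignored;
# ties keep the centre value)
mode_filter <- function(v, k) {
  if (k <= 1) return(v)
  h <- (k - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - h):min(n, i + h)]
    w <- w[!is.na(w)]
    if (length(w) == 0 || is.na(v[i])) return(v[i])
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    if (v[i] %in% top) v[i] else top[1]
  }, character(1))
}

# per-frame combined motion (step + heading change in sector widths) for
# one animal, from the kinematics tibble
frame_motion <- function(ds, animal) {
  k <- ds$kinematics[ds$kinematics$animal == animal, ]
  k <- k[order(k$frame), ]
  w <- 360 / ds$params$n_sectors
  m <- abs(k$d_heading) / w + k$step_mag
  m[is.na(m)] <- 0
  m
}

#' Detect joint intervals
#'
#' Maximal runs of a constant (optionally mode-smoothed) code of length at
#' least `min_duration`. Undefined frames break runs. An interval is
#' *dynamic* — an attractor rather than a static posture — when the
#' animals' combined motion averages at least `motion_floor` per frame
#' over the interval. The compensation index is filled for intervals with
#' non-zero motion.
#'
#' @param ds a `dyad_series`.
#' @param measure `"partnerwise"`, `"opposition"` or `"combined"` (the
#'   sector/opposition tuple).
#' @param min_duration minimum run length in frames (>= 2).
#' @param motion_floor per-frame combined-motion threshold for the dynamic
#'   flag. Motion per frame and animal is
#'   `step_mag + |d_heading| / sector_width`, i.e. body lengths plus
#'   heading change in sector widths.
#' @param smooth_k odd mode-filter width applied to the discretized code
#'   series before run detection (1 = off). This is the only place the
#'   discretized series is altered.
#' @param focal focal animal (defaults to the first, sorted).
#' @return tibble of intervals: `measure`, `start`, `end` (half-open frame
#'   range), `code`, `duration`, `motion_a`, `motion_b` (summed combined
#'   motion per animal), `dynamic`, `ci` (compensation index, `NA` for
#'   zero-motion intervals), `maintainer` (`"static"` for non-dynamic
#'   intervals, otherwise `NA` until [classify_maintenance()] is run).
#' @export
detect_joints <- function(ds, measure = "partnerwise", min_duration = 5,
                          motion_floor = 0.02, smooth_k = 1, focal = NULL) {
  stopifnot(min_duration >= 2)
  ans <- sort(unique(ds$measures$focal))
  focal <- focal %||% ans[1]
  partner <- setdiff(ans, focal)
  codes <- mode_filter(code_series(ds, measure, focal), smooth_k)
  mot_a <- frame_motion(ds, focal)
  mot_b <- frame_motion(ds, partner)

  r <- rle(ifelse(is.na(codes), "\r<NA>", codes))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_duration & r$values != "\r<NA>"
  if (!any(keep)) {
    return(tibble::tibble(measure = character(), start = integer(),
                          end = integer(), code = character(),
                          duration = integer(), motion_a = numeric(),
                          motion_b = numeric(), dynamic = logical(),
                          ci = numeric(), maintainer = character()))
  }
  s0 <- starts[keep] - 1L   # 0-based start frame
  e0 <- ends[keep]          # half-open end
  # motion within [start, end): frame-to-frame changes landing inside
  msum <- function(mot, s, e) sum(mot[(s + 2L):e], na.rm = TRUE)
  motion_a <- mapply(msum, s = s0, e = e0, MoreArgs = list(mot = mot_a))
  motion_b <- mapply(msum, s = s0, e = e0, MoreArgs = list(mot = mot_b))
  duration <- e0 - s0
  dynamic <- (motion_a + motion_b) >= motion_floor * duration
  ci <- mapply(function(s, e) compensation_index(ds, s, e, focal),
               s = s0, e = e0)
  tibble::tibble(
    measure = measure, start = as.integer(s0), end = as.integer(e0),
    code = r$values[keep], duration = as.integer(duration),
    motion_a = motion_a, motion_b = motion_b, dynamic = dynamic,
    ci = ci,
    maintainer = ifelse(dynamic, NA_character_, "static")
  )
}

#' Compensation index of an interval
#'
#' Measures how much of the animals' motion cancels out relationally:
#' `ci = 1 - min(1, R / M)` where `R` is the relational path length over
#' the interval (summed absolute changes of the relative heading in
#' sector widths plus summed absolute changes of relative distance in
#' body lengths) and `M` the total motion of both animals in the same
#' units (heading changes in sector widths plus step lengths). Perfectly
#' mirrored pursuit — the relational state exactly constant while both
#' animals move — gives 1; a single animal moving while all its motion
#' shows up relationally gives 0. Undefined (`NA`) for zero-motion
#' (static) intervals.
#'
#' @param ds a `dyad_series`.
#' @param start,end half-open frame interval.
#' @param focal focal animal for the relational series (the index is
#'   swap-invariant).
#' @return compensation index in `[0, 1]`, or `NA`.
#' @export
compensation_index <- function(ds, start, end, focal = NULL) {
  ans <- sort(unique(ds$measures$focal))
  focal <- focal %||% ans[1]
  partner <- setdiff(ans, focal)
  m <- ds$measures[ds$measures$focal == focal, ]
  m <- m[order(m$frame), ]
  idx <- (start + 2L):end            # changes landing inside [start,end)
  if (start + 2L > end) return(NA_real_)
  w <- 360 / ds$params$n_sectors
  drel <- abs(wrap180(diff(m$rel_heading)))[idx - 1L] / w
  ddist <- abs(diff(m$rel_distance))[idx - 1L]
  r_len <- sum(drel, na.rm = TRUE) + sum(ddist, na.rm = TRUE)
  mot <- sum(frame_motion(ds, focal)[idx], na.rm = TRUE) +
    sum(frame_motion(ds, partner)[idx], na.rm = TRUE)
  if (mot <= 0) return(NA_real_)
  1 - min(1, r_len / mot)
}

# --- counterfactual machinery -------------------------------------------

# pose matrices per animal per frame (list of arrays)
dyad_poses <- function(ts, bm) {
  ans <- animals(ts)
  parts <- union(bm$midline, bm$heading)
  lapply(stats::setNames(ans, ans), track_array, ts = ts, parts = parts)
}

# measure code from two explicit poses
pair_code <- function(pose_f, pose_p, bm, measure, n_sectors) {
  hf <- heading_angle(pose_f, bm)
  hp <- heading_angle(pose_p, bm)
  pf <- midline_polyline(pose_f, bm)
  pp <- midline_polyline(pose_p, bm)
  pw <- if (is.na(hf) || is.na(hp)) NA_integer_ else
    sectorize(wrap360(hp - hf), n_sectors)
  if (measure == "partnerwise") return(as.character(pw))
  opp <- opposition(pf, pp, bm)
  ol <- if (is.na(opp$opp_focal)) NA_character_ else
    paste0(opp$opp_focal, "/", opp$opp_partner)
  if (measure == "opposition") ol else paste0(pw, "|", ol)
}

# combined motion of one animal between two frames (1-based indices)
window_motion <- function(arr, i0, i1, bm, ref, w) {
  p0 <- frame_pose(arr, i0); p1 <- frame_pose(arr, i1)
  h0 <- heading_angle(p0, bm); h1 <- heading_angle(p1, bm)
  m0 <- midline_polyline(p0, bm); m1 <- midline_polyline(p1, bm)
  if (is.na(h0) || is.na(h1) || is.null(m0) || is.null(m1)) return(NA_real_)
  dth <- abs(wrap180(h1 - h0)) / w
  dstep <- sqrt(sum((colMeans(m1$vertices) - colMeans(m0$vertices))^2)) / ref
  dth + dstep
}

#' Attribute a configurational transition to its producer
#'
#' Given a frame `t` at which the measure code differs from its value at
#' `t - window`, evaluates the two counterfactual freezes: the code with
#' the focal animal at `t` and the partner frozen at `t - window`
#' (`cf_focal`), and the mirror (`cf_partner`). The transition is
#' attributed to the focal animal if its motion alone reproduces the new
#' code while the frozen-focal counterfactual retains the old one; to the
#' partner in the mirrored case; to `both` when either animal's motion
#' alone suffices; otherwise — including when the implied mover's motion
#' over the window is below `motion_floor` per frame (a sub-floor jitter
#' flip) — it is `ambiguous`.
#'
#' @param ts a `track_set` (the same data the series was computed from).
#' @param ds a `dyad_series` (supplies reference lengths and params).
#' @param t transition frame (0-based); requires `t - window >= 0`.
#' @param window counterfactual look-back in frames (default 3: single-
#'   frame counterfactuals are noise-dominated at typical frame rates).
#' @param measure `"partnerwise"`, `"opposition"` or `"combined"`.
#' @param motion_floor minimum per-frame combined motion for the mover.
#' @param focal focal animal.
#' @return one-row tibble: `frame`, `measure`, `from_code`, `to_code`,
#'   `attribution` (`focal`/`partner`/`both`/`ambiguous`), `cf_focal`,
#'   `cf_partner` (the counterfactual codes), `motion_focal`,
#'   `motion_partner` (window motion per animal).
#' @export
attribute_transition <- function(ts, ds, t, window = 3,
                                 measure = "partnerwise",
                                 motion_floor = 0.02, focal = NULL) {
  if (t - window < 0) {
    stop("t - window is before the first frame", call. = FALSE)
  }
  ans <- sort(unique(ds$measures$focal))
  focal <- focal %||% ans[1]
  partner <- setdiff(ans, focal)
  bm <- ds$bm
  n_sectors <- ds$params$n_sectors
  w <- 360 / n_sectors
  poses <- dyad_poses(ts, bm)
  i1 <- t + 1L            # 1-based array rows
  i0 <- t - window + 1L
  pf1 <- frame_pose(poses[[focal]], i1)
  pf0 <- frame_pose(poses[[focal]], i0)
  pp1 <- frame_pose(poses[[partner]], i1)
  pp0 <- frame_pose(poses[[partner]], i0)

  from_code <- pair_code(pf0, pp0, bm, measure, n_sectors)
  to_code <- pair_code(pf1, pp1, bm, measure, n_sectors)
  cf_focal <- pair_code(pf1, pp0, bm, measure, n_sectors)   # partner frozen
  cf_partner <- pair_code(pf0, pp1, bm, measure, n_sectors) # focal frozen

  mot_f <- window_motion(poses[[focal]], i0, i1, bm,
                         ds$ref_lengths[[focal]], w)
  mot_p <- window_motion(poses[[partner]], i0, i1, bm,
                         ds$ref_lengths[[partner]], w)
  floor_w <- motion_floor * window

  attribution <- "ambiguous"
  if (!is.na(from_code) && !is.na(to_code) && from_code != to_code) {
    f_alone <- identical(cf_focal, to_code)
    p_alone <- identical(cf_partner, to_code)
    f_inert <- identical(cf_partner, from_code)
    p_inert <- identical(cf_focal, from_code)
    if (f_alone && p_alone) {
      attribution <- "both"
      if (isTRUE(mot_f + mot_p < floor_w)) attribution <- "ambiguous"
    } else if (f_alone && f_inert) {
      attribution <- if (isTRUE(mot_f >= floor_w)) "focal" else "ambiguous"
    } else if (p_alone && p_inert) {
      attribution <- if (isTRUE(mot_p >= floor_w)) "partner" else "ambiguous"
    }
  }
  tibble::tibble(frame = as.integer(t), measure = measure,
                 from_code = from_code, to_code = to_code,
                 attribution = attribution,
                 cf_focal = cf_focal, cf_partner = cf_partner,
                 motion_focal = mot_f, motion_partner = mot_p)
}

#' Detect and attribute all transitions in a series
#'
#' Finds every frame where the (optionally smoothed) code changes between
#' defined frames and attributes each change with
#' [attribute_transition()]. Changes closer than `window` to the start of
#' the recording are skipped.
#'
#' @inheritParams attribute_transition
#' @param smooth_k mode-filter width for change detection (1 = off).
#' @return tibble of attributed transitions (possibly empty).
#' @export
attribute_transitions <- function(ts, ds, measure = "partnerwise",
                                  window = 3, motion_floor = 0.02,
                                  smooth_k = 1, focal = NULL) {
  codes <- mode_filter(code_series(ds, measure, focal), smooth_k)
  n <- length(codes)
  chg <- which(codes[-1] != codes[-n] & !is.na(codes[-1]) &
                 !is.na(codes[-n]))   # change between frame chg-1 and chg
  frames <- chg                       # 0-based frame of the new code
  frames <- frames[frames - window >= 0]
  purrr::map_dfr(frames, function(t) {
    attribute_transition(ts, ds, t, window = window, measure = measure,
                         motion_floor = motion_floor, focal = focal)
  })
}

#' Classify who maintains a dynamic joint
#'
#' For each interior frame of the interval, tests whether freezing one
#' animal `window` frames in the past (with the other played back) would
#' change the code: if so, that animal's ongoing movement was *necessary*
#' at that frame. The joint is `mutual` when both necessity fractions
#' reach `tau` (both animals' compensation is load-bearing, as in a
#' mutually blocked stand-off); otherwise it is assigned to the animal
#' with the dominant necessity fraction (the partner who keeps overcoming
#' the other's manoeuvres); `static` when neither reaches `tau`.
#'
#' @inheritParams attribute_transition
#' @param start,end half-open frame interval of the joint.
#' @param tau necessity-fraction threshold for `mutual` (default 0.25; a
#'   tunable with no principled value — see the methods vignette).
#' @return one-row tibble: `maintainer` (`mutual`/`focal`/`partner`/
#'   `static`), `necessity_focal`, `necessity_partner`.
#' @export
classify_maintenance <- function(ts, ds, start, end, window = 10,
                                 measure = "partnerwise", tau = 0.25,
                                 focal = NULL) {
  if (end - start <= window) {
    stop("joint interval shorter than the counterfactual window",
         call. = FALSE)
  }
  ans <- sort(unique(ds$measures$focal))
  focal <- focal %||% ans[1]
  partner <- setdiff(ans, focal)
  bm <- ds$bm
  n_sectors <- ds$params$n_sectors
  poses <- dyad_poses(ts, bm)
  frames <- (start + window):(end - 1L)
  nec_f <- logical(length(frames))
  nec_p <- logical(length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    i1 <- t + 1L; i0 <- t - window + 1L
    pf1 <- frame_pose(poses[[focal]], i1)
    pf0 <- frame_pose(poses[[focal]], i0)
    pp1 <- frame_pose(poses[[partner]], i1)
    pp0 <- frame_pose(poses[[partner]], i0)
    actual <- pair_code(pf1, pp1, bm, measure, n_sectors)
    froz_f <- pair_code(pf0, pp1, bm, measure, n_sectors)
    froz_p <- pair_code(pf1, pp0, bm, measure, n_sectors)
    nec_f[k] <- !identical(froz_f, actual)
    nec_p[k] <- !identical(froz_p, actual)
  }
  ff <- mean(nec_f); fp <- mean(nec_p)
  maintainer <- if (ff >= tau && fp >= tau) "mutual"
    else if (max(ff, fp) >= tau) {
      if (ff > fp) "focal" else "partner"
    } else "static"
  tibble::tibble(maintainer = maintainer,
                 necessity_focal = ff, necessity_partner = fp)
}

#' @importFrom rlang %||% .data
NULL
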