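#' Dyadic relational measures
#'
#' Three simplified horizontal-plane EWMN measures describe the
#' configuration of a dyad at each frame:
#'
#' * **Partnerwise orientation** — the direction in which the partner's
#'   longitudinal axis points, expressed as a sector on the EWMN ring
#'   centred on the focal animal's facing direction (sector 4 =
#'   anti-parallel).
#' * **Opposition** — the pair of body-surface codes at the two animals'
#'   mutually closest body points (e.g. `"2H/2H"` = right side of head
#'   against right side of head).
#' * **Relative distance** — the gap between the two midlines expressed in
#'   body lengths, so that measures are comparable across arenas filmed
#'   without a metric reference.
#'
#' @name relational
NULL

#' Partnerwise orientation
#'
#' @param heading_focal,heading_partner headings in degrees (clockwise
#'   from +y), as from [heading_angle()].
#' @param n_sectors 8 or 16.
#' @return a one-row tibble with `rel_heading` (clockwise angle from the
#'   focal heading to the partner heading, degrees `[0, 360)`) and
#'   `partnerwise` (its sector code). `NA`s propagate.
#' @examples
#' partnerwise(0, 180)    # anti-parallel: sector 4
#' @export
partnerwise <- function(heading_focal, heading_partner, n_sectors = 8) {
  rel <- wrap360(heading_partner - heading_focal)
  tibble::tibble(rel_heading = rel,
                 partnerwise = sectorize(rel, n_sectors))
}

#' Opposition codes and gap at the closest approach
#'
#' Finds the exact closest pair of points between the two midline
#' polylines and scores each animal's body surface at that pair: the
#' focal code is the surface coordinate of the partner's closest point
#' relative to the focal polyline, and vice versa.
#'
#' @param poly_focal,poly_partner `midline_polyline`s.
#' @param bm a [body_model()].
#' @return one-row tibble: `opp_focal`, `opp_partner` (surface labels such
#'   as `"0"` or `"2H"`), `gap` (arena units), plus focal/partner arc
#'   fractions and segments of the closest points.
#' @export
opposition <- function(poly_focal, poly_partner, bm) {
  if (is.null(poly_focal) || is.null(poly_partner)) {
    return(tibble::tibble(opp_focal = NA_character_,
                          opp_partner = NA_character_, gap = NA_real_,
                          arc_focal = NA_real_, arc_partner = NA_real_,
                          seg_focal = NA_integer_, seg_partner = NA_integer_))
  }
  o <- opposition_core(poly_focal, poly_partner, bm)
  tibble::tibble(opp_focal = o$opp_focal, opp_partner = o$opp_partner,
                 gap = o$gap,
                 arc_focal = o$arc_focal, arc_partner = o$arc_partner,
                 seg_focal = o$seg_focal, seg_partner = o$seg_partner)
}

# list-returning core of opposition (hot path)
opposition_core <- function(poly_focal, poly_partner, bm) {
  if (is.null(poly_focal) || is.null(poly_partner)) {
    return(list(opp_focal = NA_character_, opp_partner = NA_character_,
                gap = NA_real_, arc_focal = NA_real_,
                arc_partner = NA_real_, seg_focal = NA_integer_,
                seg_partner = NA_integer_))
  }
  cp <- closest_pair_polylines(poly_focal, poly_partner)
  sf <- surface_core(poly_focal, cp$q, bm)
  sp <- surface_core(poly_partner, cp$p, bm)
  list(opp_focal = sf$label, opp_partner = sp$label, gap = cp$gap,
       arc_focal = sf$arc_fraction, arc_partner = sp$arc_fraction,
       seg_focal = sf$segment, seg_partner = sp$segment)
}

#' Relative distance in body lengths
#'
#' @param gap closest-approach distance, arena units.
#' @param ref reference body length (arena units), see
#'   [reference_length()].
#' @return `gap / ref` (body lengths).
#' @export
relative_distance <- function(gap, ref) {
  if (any(!is.na(ref) & ref <= 0)) {
    stop("reference length must be positive", call. = FALSE)
  }
  gap / ref
}

#' Per-animal Front/Weight kinematic codes
#'
#' `front` is the allocentric facing-direction sector (the EWMN "Front"
#' row); `weight_code` the egocentric step-direction sector (the "Weight"
#' row, `S[k]`): the sector of the displacement vector measured clockwise
#' from the animal's own heading, so a step to the animal's left is code 6
#' and an oblique left-rear step code 5. Displacement is the backward
#' frame-to-frame difference of the midline centroid (robust to flexion);
#' `weight_code` is reported only when the step magnitude exceeds
#' `step_floor`, suppressing jitter-driven codes.
#'
#' @param ts a `track_set` (cleaned as desired).
#' @param animal animal identifier.
#' @param bm a [body_model()].
#' @param step_floor minimum step magnitude (body lengths/frame) for a
#'   Weight code, default 0.02.
#' @param n_sectors 8 or 16.
#' @param ref reference length override (arena units); computed from the
#'   data when `NULL`.
#' @return tibble, one row per frame: `frame`, `animal`, `heading`,
#'   `front`, `d_heading` (signed wrapped change, degrees/frame),
#'   `step_mag` (body lengths/frame), `weight_code`.
#' @export
kinematics <- function(ts, animal, bm, step_floor = 0.02, n_sectors = 8,
                       ref = NULL) {
  geo <- animal_geometry(ts, animal, bm)
  if (is.null(ref)) ref <- geo$ref
  t_n <- length(geo$heading)
  head <- geo$heading
  cent <- geo$centroid
  dxy <- rbind(c(NA, NA), diff(cent))
  step_mag <- sqrt(rowSums(dxy^2)) / ref
  step_dir <- bearing_cw(dxy[, 1], dxy[, 2])
  d_heading <- c(NA, wrap180(diff(head)))
  weight_angle <- wrap360(step_dir - head)
  weight_code <- sectorize(weight_angle, n_sectors)
  weight_code[is.na(step_mag) | step_mag <= step_floor] <- NA_integer_
  tibble::tibble(
    frame = 0:(t_n - 1L), animal = animal,
    heading = head, front = sectorize(head, n_sectors),
    d_heading = d_heading, step_mag = step_mag,
    weight_code = weight_code
  )
}

# Internal: per-frame polylines, headings, centroids and reference length
# for one animal.
animal_geometry <- function(ts, animal, bm) {
  arr <- track_array(ts, animal, union(bm$midline, bm$heading))
  t_n <- dim(arr)[1]
  polys <- vector("list", t_n)
  heading <- numeric(t_n)
  centroid <- matrix(NA_real_, t_n, 2)
  for (i in seq_len(t_n)) {
    pose <- frame_pose(arr, i)
    polys[[i]] <- midline_polyline(pose, bm)
    heading[i] <- heading_angle(pose, bm)
    if (!is.null(polys[[i]])) {
      centroid[i, ] <- colMeans(polys[[i]]$vertices)
    }
  }
  lens <- vapply(polys, function(p) if (is.null(p)) NA_real_ else p$length,
                 numeric(1))
  if (all(is.na(lens))) {
    stop("no frame with a defined midline for animal ", animal,
         call. = FALSE)
  }
  list(polys = polys, heading = heading, centroid = centroid,
       ref = stats::median(lens, na.rm = TRUE))
}

#' Compute the full per-frame relational series for a dyad
#'
#' Drives the whole measure pipeline over a two-animal track set: per-frame
#' midlines, headings, partnerwise sectors, opposition codes, gap and
#' relative distance for both ordered (focal, partner) pairs, plus
#' per-animal Front/Weight kinematics. Frames with undefined geometry are
#' flagged (`defined = FALSE`), never dropped.
#'
#' @param ts a `track_set` with exactly 2 animals.
#' @param bm a [body_model()].
#' @param n_sectors 8 or 16.
#' @param step_floor Weight-code step floor, body lengths/frame.
#' @param contact_tau contact-flag threshold on relative distance, body
#'   lengths (default 0.10).
#' @param distance_ref whose reference length normalises the gap:
#'   `"focal"` (default), `"partner"` or `"mean"`.
#' @return a `dyad_series` object: list with
#'   * `measures`: tibble, one row per frame x ordered pair — `frame`,
#'     `focal`, `partner`, `rel_heading`, `partnerwise`, `opp_focal`,
#'     `opp_partner`, `opposition` (the `"2H/2H"`-style pair label),
#'     `gap`, `rel_distance`, `contact`, `defined`;
#'   * `kinematics`: tibble, one row per frame x animal (see
#'     [kinematics()]);
#'   * `ref_lengths`: named reference lengths (arena units);
#'   * `params`, `bm`: the configuration used.
#' @export
relational_series <- function(ts, bm, n_sectors = 8, step_floor = 0.02,
                              contact_tau = 0.10,
                              distance_ref = c("focal", "partner", "mean")) {
  distance_ref <- match.arg(distance_ref)
  ans <- animals(ts)
  if (length(ans) != 2) {
    stop("relational_series needs exactly 2 animals, got ", length(ans),
         call. = FALSE)
  }
  geo <- lapply(stats::setNames(ans, ans), animal_geometry, ts = ts, bm = bm)
  refs <- vapply(geo, `[[`, numeric(1), "ref")
  t_n <- length(geo[[1]]$heading)

  ks <- dplyr::bind_rows(lapply(ans, function(a) {
    kin_from_geometry(geo[[a]], a, step_floor, n_sectors)
  }))

  # per-frame symmetric quantities, computed once
  rel_ab <- wrap360(geo[[2]]$heading - geo[[1]]$heading)
  opp <- list(opp_focal = rep(NA_character_, t_n),
              opp_partner = rep(NA_character_, t_n),
              gap = rep(NA_real_, t_n))
  for (i in seq_len(t_n)) {
    o <- opposition_core(geo[[1]]$polys[[i]], geo[[2]]$polys[[i]], bm)
    opp$opp_focal[i] <- o$opp_focal
    opp$opp_partner[i] <- o$opp_partner
    opp$gap[i] <- o$gap
  }

  ref_for <- function(focal, partner) {
    switch(distance_ref,
           focal = refs[[focal]],
           partner = refs[[partner]],
           mean = mean(refs))
  }
  make_pair <- function(focal, partner, rel, opp_f, opp_p) {
    rd <- relative_distance(opp$gap, ref_for(focal, partner))
    tibble::tibble(
      frame = 0:(t_n - 1L), focal = focal, partner = partner,
      rel_heading = rel, partnerwise = sectorize(rel, n_sectors),
      opp_focal = opp_f, opp_partner = opp_p,
      opposition = ifelse(is.na(opp_f), NA_character_,
                          paste0(opp_f, "/", opp_p)),
      gap = opp$gap, rel_distance = rd,
      contact = !is.na(rd) & rd <= contact_tau,
      defined = !is.na(rel) & !is.na(opp_f)
    )
  }
  measures <- dplyr::bind_rows(
    make_pair(ans[1], ans[2], rel_ab, opp$opp_focal, opp$opp_partner),
    make_pair(ans[2], ans[1], wrap360(-rel_ab), opp$opp_partner,
              opp$opp_focal)
  )

  structure(
    list(measures = measures, kinematics = ks, ref_lengths = refs,
         params = list(n_sectors = n_sectors, step_floor = step_floor,
                       contact_tau = contact_tau,
                       distance_ref = distance_ref),
         bm = bm, fps = attr(ts, "fps")),
    class = "dyad_series"
  )
}

# kinematics from a precomputed animal_geometry (avoids recomputation)
kin_from_geometry <- function(g, animal, step_floor, n_sectors) {
  t_n <- length(g$heading)
  dxy <- rbind(c(NA, NA), diff(g$centroid))
  step_mag <- sqrt(rowSums(dxy^2)) / g$ref
  step_dir <- bearing_cw(dxy[, 1], dxy[, 2])
  d_heading <- c(NA, wrap180(diff(g$heading)))
  weight_code <- sectorize(wrap360(step_dir - g$heading), n_sectors)
  weight_code[is.na(step_mag) | step_mag <= step_floor] <- NA_integer_
  tibble::tibble(frame = 0:(t_n - 1L), animal = animal,
                 heading = g$heading, front = sectorize(g$heading, n_sectors),
                 d_heading = d_heading, step_mag = step_mag,
                 weight_code = weight_code)
}

#' @export
print.dyad_series <- function(x, ...) {
  a <- unique(x$measures$focal)
  cat(sprintf("<dyad_series> %d frames, animals %s; %d/%d frames defined\n",
              max(x$measures$frame) + 1, paste(a, collapse = " & "),
              sum(x$measures$defined[x$measures$focal == a[1]]),
              max(x$measures$frame) + 1))
  cat("reference lengths:",
      paste(names(x$ref_lengths), round(x$ref_lengths, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dyad series into its per-frame measures
#'
#' @param x a `dyad_series`.
#' @param ... unused.
#' @return the `measures` tibble (one row per frame x ordered pair).
#' @method tidy dyad_series
#' @export
tidy.dyad_series <- function(x, ...) x$measures

#' One-row summary of a dyad series
#'
#' @param x a `dyad_series`.
#' @param ... unused.
#' @return tibble with frame counts, defined fraction, mean relative
#'   distance, modal partnerwise sector and contact fraction.
#' @method glance dyad_series
#' @export
glance.dyad_series <- function(x, ...) {
  m <- x$measures[x$measures$focal == sort(unique(x$measures$focal))[1], ]
  pw <- m$partnerwise[!is.na(m$partnerwise)]
  tibble::tibble(
    n_frames = nrow(m),
    prop_defined = mean(m$defined),
    mean_rel_distance = mean(m$rel_distance, na.rm = TRUE),
    modal_partnerwise = if (length(pw)) as.integer(names(
      sort(table(pw), decreasing = TRUE))[1]) else NA_integer_,
    prop_contact = mean(m$contact, na.rm = TRUE)
  )
}

#' Plot a dyad series
#'
#' Time courses of the three relational measures for the first focal
#' animal: partnerwise sector (step trace), relative distance, and contact
#' flags.
#'
#' @param object a `dyad_series`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dyad_series
#' @export
autoplot.dyad_series <- function(object, ...) {
  m <- object$measures
  m <- m[m$focal == sort(unique(m$focal))[1], ]
  long <- dplyr::bind_rows(
    tibble::tibble(frame = m$frame, measure = "partnerwise sector",
                   value = as.numeric(m$partnerwise)),
    tibble::tibble(frame = m$frame, measure = "relative distance (BL)",
                   value = m$rel_distance),
    tibble::tibble(frame = m$frame, measure = "contact",
                   value = as.numeric(m$contact))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
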