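#' Contact events and body-target scoring
#'
#' Tracks a designated actor point (e.g. the head, or the tip of the
#' abdomen) of one animal against the partner's midline, detects contact
#' events, bins their targets into equal arc-length body segments
#' (segment 1 = head end), and summarises how contacts shift along the
#' recipient's body.
#'
#' @name contacts
NULL

#' Detect contact events
#'
#' A frame is in contact when the actor point lies within `tau_contact`
#' body lengths (of the recipient's reference length) of the recipient's
#' midline. Contact frames are grouped into runs; runs separated by at
#' most `merge_gap` frames are merged; merged runs shorter than `n_min`
#' frames are discarded.
#'
#' @param ts a `track_set`.
#' @param bm a [body_model()].
#' @param actor,recipient animal identifiers.
#' @param actor_point bodypart of the actor making contact.
#' @param tau_contact contact threshold in recipient body lengths
#'   (default 0.10).
#' @param n_min minimum event length in frames (default 3).
#' @param merge_gap maximum separating gap to merge, frames (default 2).
#' @return tibble of events: `actor`, `recipient`, `actor_point`,
#'   `start`, `end` (half-open frames), `start_segment`, `end_segment`,
#'   `start_code`, `end_code` (recipient surface labels), `min_gap`
#'   (closest approach over the event, body lengths), `n_frames`.
#'   The detection parameters are attached as the `params` attribute.
#' @export
detect_contacts <- function(ts, bm, actor, recipient,
                            actor_point = bm$midline[1],
                            tau_contact = 0.10, n_min = 3, merge_gap = 2) {
  if (!actor_point %in% bodyparts(ts)) {
    stop("actor_point `", actor_point, "` is not a tracked bodypart",
         call. = FALSE)
  }
  per <- contact_frames(ts, bm, actor, recipient, actor_point)
  ref <- reference_length(ts, recipient, bm)
  rel <- per$dist / ref
  hit <- !is.na(rel) & rel <= tau_contact

  runs <- merge_runs(hit, merge_gap)
  if (nrow(runs) > 0) runs <- runs[runs$end - runs$start >= n_min, ]
  events <- purrr::pmap_dfr(runs, function(start, end) {
    i0 <- start + 1L; i1 <- end          # 1-based rows
    tibble::tibble(
      actor = actor, recipient = recipient, actor_point = actor_point,
      start = as.integer(start), end = as.integer(end),
      start_segment = per$segment[i0], end_segment = per$segment[i1],
      start_code = per$label[i0], end_code = per$label[i1],
      min_gap = min(rel[i0:i1], na.rm = TRUE),
      n_frames = as.integer(end - start)
    )
  })
  if (nrow(events) == 0) {
    events <- tibble::tibble(actor = character(), recipient = character(),
                             actor_point = character(), start = integer(),
                             end = integer(), start_segment = integer(),
                             end_segment = integer(), start_code = character(),
                             end_code = character(), min_gap = numeric(),
                             n_frames = integer())
  }
  attr(events, "params") <- list(tau_contact = tau_contact, n_min = n_min,
                                 merge_gap = merge_gap,
                                 actor_point = actor_point)
  attr(events, "per_frame") <- per
  events
}

# per-frame actor-point-to-recipient-midline geometry
contact_frames <- function(ts, bm, actor, recipient, actor_point) {
  arr_a <- track_array(ts, actor, actor_point)
  geo_r <- animal_geometry(ts, recipient, bm)
  t_n <- dim(arr_a)[1]
  dist <- rep(NA_real_, t_n)
  segment <- rep(NA_integer_, t_n)
  label <- rep(NA_character_, t_n)
  arcf <- rep(NA_real_, t_n)
  for (i in seq_len(t_n)) {
    p <- c(arr_a[i, 1, 1], arr_a[i, 1, 2])
    poly <- geo_r$polys[[i]]
    if (is.null(poly) || anyNA(p)) next
    sc <- surface_core(poly, p, bm)
    dist[i] <- sc$dist
    segment[i] <- sc$segment
    label[i] <- sc$label
    arcf[i] <- sc$arc_fraction
  }
  tibble::tibble(frame = 0:(t_n - 1L), dist = dist, segment = segment,
                 label = label, arc_fraction = arcf)
}

# logical vector -> half-open 0-based runs, gaps <= merge_gap merged
merge_runs <- function(hit, merge_gap) {
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  if (nrow(runs) <= 1) return(runs)
  merged <- runs[1, ]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged
}

#' Segment histogram of contact targets
#'
#' @param events tibble from [detect_contacts()].
#' @param n_segments number of body segments (must match the body model).
#' @param weight `"events"` (default: each event counts once, by its
#'   start segment) or `"frames"` (events weighted by their duration).
#' @return tibble with `segment` (1..n_segments) and `percent`; the
#'   percentages sum to 100 when any events exist, and are all zero (with
#'   a warning) when none do.
#' @export
segment_histogram <- function(events, n_segments = 4,
                              weight = c("events", "frames")) {
  weight <- match.arg(weight)
  out <- tibble::tibble(segment = seq_len(n_segments), percent = 0)
  if (nrow(events) == 0) {
    warning("no contact events; returning an all-zero histogram",
            call. = FALSE)
    return(out)
  }
  w <- if (weight == "events") rep(1, nrow(events)) else events$n_frames
  tot <- tapply(w, factor(events$start_segment,
                          levels = seq_len(n_segments)), sum)
  tot[is.na(tot)] <- 0
  out$percent <- 100 * as.numeric(tot) / sum(tot)
  out
}

#' Start-to-end shift map of contacts
#'
#' Where contacts begin versus where they end on the recipient's body:
#' counts of (start segment, end segment) and the mean signed segment
#' shift, negative meaning contact slid anteriorly (towards the head).
#'
#' @param events tibble from [detect_contacts()].
#' @return list with `transitions` (tibble `start_segment`, `end_segment`,
#'   `n`) and `mean_shift` (mean of `end_segment - start_segment`).
#' @export
shift_map <- function(events) {
  if (nrow(events) == 0) {
    return(list(transitions = tibble::tibble(start_segment = integer(),
                                             end_segment = integer(),
                                             n = integer()),
                mean_shift = NA_real_))
  }
  tr <- events |>
    dplyr::count(.data$start_segment, .data$end_segment, name = "n")
  list(transitions = tr,
       mean_shift = mean(events$end_segment - events$start_segment))
}

#' Opposition-transition topography
#'
#' Builds the transition graph over opposition (or other measure) codes:
#' nodes are the observed codes, directed edges count transitions, and
#' each edge carries the mix of attributions — whether both animals moved
#' (`both_moved`), only the partner (`partner_only`), or only the focal
#' animal (`focal_only`) — echoing the solid/dashed distinction of
#' topographic opposition summaries.
#'
#' @param transitions tibble from [attribute_transitions()].
#' @return a `transition_graph`: list with `nodes` (tibble `code`, `n`)
#'   and `edges` (tibble `from`, `to`, `n`, `both_moved`, `focal_only`,
#'   `partner_only`, `ambiguous`; the four fractions sum to 1 per edge).
#' @export
opposition_topography <- function(transitions) {
  if (nrow(transitions) == 0) {
    g <- list(nodes = tibble::tibble(code = character(), n = integer()),
              edges = tibble::tibble(from = character(), to = character(),
                                     n = integer(), both_moved = numeric(),
                                     focal_only = numeric(),
                                     partner_only = numeric(),
                                     ambiguous = numeric()))
    class(g) <- "transition_graph"
    return(g)
  }
  edges <- transitions |>
    dplyr::group_by(from = .data$from_code, to = .data$to_code) |>
    dplyr::summarise(
      n = dplyr::n(),
      both_moved = mean(.data$attribution == "both"),
      focal_only = mean(.data$attribution == "focal"),
      partner_only = mean(.data$attribution == "partner"),
      ambiguous = mean(.data$attribution == "ambiguous"),
      .groups = "drop"
    )
  nodes <- tibble::tibble(code = c(transitions$from_code,
                                   transitions$to_code)) |>
    dplyr::count(.data$code, name = "n")
  g <- list(nodes = nodes, edges = edges)
  class(g) <- "transition_graph"
  g
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$edges)
  invisible(x)
}

#' Tidy a transition graph into its edge list
#' @param x a `transition_graph`.
#' @param ... unused.
#' @return the edges tibble.
#' @method tidy transition_graph
#' @export
tidy.transition_graph <- function(x, ...) x$edges

#' Serialize a transition graph to node-link JSON
#' @param g a `transition_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topography_json <- function(g, path) {
  jsonlite::write_json(list(nodes = g$nodes, links = g$edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bar plot of a segment histogram
#'
#' @param hist tibble from [segment_histogram()].
#' @return a ggplot object.
#' @export
plot_segment_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$segment),
                                     y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "body segment (1 = head)", y = "% of contacts") +
    ggplot2::theme_minimal()
}

#' Plot a transition graph
#'
#' Nodes on a circle; edge line type distinguishes transitions produced
#' by both animals (solid) from single-animal ones (dashed).
#'
#' @param object a `transition_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot transition_graph
#' @export
autoplot.transition_graph <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  if (k == 0) return(ggplot2::ggplot())
  ang <- 2 * pi * (seq_len(k) - 1) / k
  nodes$px <- cos(ang); nodes$py <- sin(ang)
  e <- dplyr::left_join(object$edges,
                        dplyr::select(nodes, "code", fx = "px", fy = "py"),
                        by = c(from = "code"))
  e <- dplyr::left_join(e,
                        dplyr::select(nodes, "code", tx = "px", ty = "py"),
                        by = c(to = "code"))
  e$style <- ifelse(e$both_moved >= 0.5, "both", "single")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$fx, y = .data$fy, xend = .data$tx,
                   yend = .data$ty, linewidth = .data$n,
                   linetype = .data$style),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      colour = "grey40") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$px, y = .data$py,
                                     label = .data$code)) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::theme_void()
}
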