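#' Score detections against simulator ground truth
#'
#' Standard overlap/accuracy metrics with a greedy best-overlap matching
#' rule: truth intervals are visited longest-first and matched to the
#' unused detected interval with the highest Jaccard overlap.
#'
#' @name truth_alignment
NULL

#' Ground-truth joint intervals of a simulation
#'
#' Maximal constant-code runs of the scripted (noise-free) measure
#' series, length at least `min_duration`.
#'
#' @param sim a `dyad_sim`.
#' @param measure `"partnerwise"` or `"opposition"`.
#' @param min_duration minimum run length, frames.
#' @return tibble `start`, `end` (half-open), `code`.
#' @export
truth_joints <- function(sim, measure = "partnerwise", min_duration = 5) {
  v <- as.character(sim$truth$frames[[measure]])
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_duration
  tibble::tibble(start = as.integer(starts[keep] - 1L),
                 end = as.integer(ends[keep]), code = r$values[keep])
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0) 0 else inter / union
}

#' Align detections with ground truth
#'
#' @param sim a `dyad_sim`.
#' @param joints optional tibble from [detect_joints()].
#' @param transitions optional tibble from [attribute_transitions()]
#'   (with the focal animal being `"a"`).
#' @param contacts optional tibble from [detect_contacts()].
#' @param measure measure the joints/transitions were detected on.
#' @param min_duration minimum truth-joint duration to score.
#' @param frame_tol matching tolerance (frames) for transitions.
#' @return list with any of:
#'   * `joints`: per-truth-joint tibble (`start`, `end`, `code`,
#'     `jaccard`, `matched`);
#'   * `transitions`: per-truth-transition tibble (`frame`, `mover`,
#'     `detected`, `attributed_to`, `correct`) — `correct` compares the
#'     attribution, mapped back to animal names, with the scripted mover;
#'   * `contacts`: list with per-truth-event matches and a
#'     `segment_confusion` table (scripted target vs detected start
#'     segment).
#' @export
truth_alignment <- function(sim, joints = NULL, transitions = NULL,
                            contacts = NULL, measure = "partnerwise",
                            min_duration = 5, frame_tol = 2) {
  t_truth <- sim$truth
  if (max(t_truth$frames$frame) + 1L != n_frames(sim$tracks)) {
    stop("truth and tracks cover different frame ranges", call. = FALSE)
  }
  out <- list()

  if (!is.null(joints)) {
    tj <- truth_joints(sim, measure, min_duration)
    tj <- tj[order(-(tj$end - tj$start)), ]
    used <- rep(FALSE, nrow(joints))
    res <- purrr::pmap_dfr(tj, function(start, end, code) {
      jac <- vapply(seq_len(nrow(joints)), function(i) {
        if (used[i] || joints$code[i] != code) return(-1)
        interval_jaccard(start, end, joints$start[i], joints$end[i])
      }, numeric(1))
      best <- if (length(jac) && max(jac) >= 0) which.max(jac) else NA
      if (!is.na(best)) used[best] <<- TRUE
      tibble::tibble(start = start, end = end, code = code,
                     jaccard = if (is.na(best)) 0 else max(jac, 0),
                     matched = !is.na(best))
    })
    out$joints <- res[order(res$start), ]
  }

  if (!is.null(transitions)) {
    focal <- "a"
    tt <- t_truth$transitions
    res <- purrr::pmap_dfr(tt, function(frame, from, to, mover) {
      cand <- transitions[abs(transitions$frame - frame) <= frame_tol, ]
      if (nrow(cand) == 0) {
        return(tibble::tibble(frame = frame, mover = mover,
                              detected = FALSE,
                              attributed_to = NA_character_,
                              correct = NA))
      }
      att <- cand$attribution[which.min(abs(cand$frame - frame))]
      att_name <- switch(att, focal = focal, partner = setdiff(c("a", "b"),
                                                               focal),
                         att)
      tibble::tibble(frame = frame, mover = mover, detected = TRUE,
                     attributed_to = att_name,
                     correct = identical(att_name, mover))
    })
    out$transitions <- res
  }

  if (!is.null(contacts)) {
    tf <- t_truth$frames
    r <- rle(tf$contact)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    tev <- tibble::tibble(start = starts[r$values] - 1L,
                          end = ends[r$values])
    tev$target <- vapply(seq_len(nrow(tev)), function(i) {
      seg <- tf$target_segment[(tev$start[i] + 1L):tev$end[i]]
      as.integer(stats::median(seg, na.rm = TRUE))
    }, integer(1))
    matches <- purrr::pmap_dfr(tev, function(start, end, target) {
      jac <- vapply(seq_len(nrow(contacts)), function(i) {
        interval_jaccard(start, end, contacts$start[i], contacts$end[i])
      }, numeric(1))
      best <- if (length(jac) && max(jac) > 0) which.max(jac) else NA
      tibble::tibble(start = start, end = end, target = target,
                     detected = !is.na(best),
                     jaccard = if (is.na(best)) 0 else max(jac),
                     detected_segment = if (is.na(best)) NA_integer_ else
                       contacts$start_segment[best])
    })
    out$contacts <- list(
      events = matches,
      segment_confusion = table(truth = matches$target,
                                detected = matches$detected_segment,
                                useNA = "ifany")
    )
  }
  out
}
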