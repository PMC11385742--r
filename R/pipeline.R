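#' End-to-end analysis pipeline
#'
#' Ties the modules together: read, clean, measure, detect joints,
#' attribute transitions, score contacts, and write a reproducible
#' artifact bundle.
#'
#' @name pipeline
NULL

#' Assemble a run configuration
#'
#' @param input path to a tracks file.
#' @param dialect input dialect: `"tidy"`, `"multi_animal_csv"`,
#'   `"single_animal_csv"`.
#' @param bm a [body_model()] (or path to its YAML config).
#' @param out_dir output directory (created if needed).
#' @param n_sectors 8 or 16.
#' @param cleaning list: `min_confidence`, `max_gap`, `smooth_window`.
#' @param joints list: `measure`, `min_duration`, `motion_floor`,
#'   `window`, `smooth_k`, `tau`.
#' @param contacts `NULL` (skip contact scoring) or a list:
#'   `actor`, `recipient`, `actor_point`, `tau_contact`, `n_min`,
#'   `merge_gap`.
#' @param step_floor,contact_tau,distance_ref see [relational_series()].
#' @param score_stride score-sheet sampling stride.
#' @param fps,image_coords input interpretation, see [read_tidy_tracks()].
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(input, dialect = "tidy", bm, out_dir,
                       n_sectors = 8,
                       cleaning = list(min_confidence = 0, max_gap = 0,
                                       smooth_window = 1),
                       joints = list(measure = "partnerwise",
                                     min_duration = 5,
                                     motion_floor = 0.02, window = 3,
                                     smooth_k = 1, tau = 0.25),
                       contacts = NULL,
                       step_floor = 0.02, contact_tau = 0.10,
                       distance_ref = "focal", score_stride = 1,
                       fps = 30, image_coords = FALSE, seed = 1) {
  if (is.character(bm)) bm <- read_body_model(bm)
  stopifnot(inherits(bm, "body_model"), n_sectors %in% c(8, 16))
  structure(list(input = input, dialect = dialect, bm = bm,
                 out_dir = out_dir, n_sectors = n_sectors,
                 cleaning = cleaning, joints = joints, contacts = contacts,
                 step_floor = step_floor, contact_tau = contact_tau,
                 distance_ref = distance_ref, score_stride = score_stride,
                 fps = fps, image_coords = image_coords, seed = seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Writes `measures.csv`, `joints.csv`, `transitions.csv`, `contacts.csv`,
#' `topography.json`, `score_sheet.txt`, `report.md` and `manifest.json`
#' into the configured output directory. Any stage error aborts with a
#' stage-named message and removes the partial outputs. Reruns on the
#' same input and config are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a named list of the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  tryCatch({
    stage <- "read"
    ts <- switch(cfg$dialect,
                 tidy = read_tidy_tracks(cfg$input, fps = cfg$fps,
                                         image_coords = cfg$image_coords),
                 read_dlc_tracks(cfg$input, dialect = cfg$dialect,
                                 fps = cfg$fps,
                                 image_coords = cfg$image_coords))
    stage <- "validate"
    known <- bodyparts(ts)
    need <- unique(c(cfg$bm$midline, cfg$bm$heading,
                     cfg$contacts$actor_point))
    bad <- setdiff(need, known)
    if (length(bad) > 0) {
      stop("config references unknown bodypart(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stage <- "clean"
    ts <- clean_tracks(ts,
                       min_confidence = cfg$cleaning$min_confidence %||% 0,
                       max_gap = cfg$cleaning$max_gap %||% 0,
                       smooth_window = cfg$cleaning$smooth_window %||% 1)
    stage <- "measure"
    ds <- relational_series(ts, cfg$bm, n_sectors = cfg$n_sectors,
                            step_floor = cfg$step_floor,
                            contact_tau = cfg$contact_tau,
                            distance_ref = cfg$distance_ref)
    emit("measures.csv", function(p)
      readr::write_csv(ds$measures, p, progress = FALSE))
    stage <- "joints"
    jp <- cfg$joints
    joints <- detect_joints(ds, measure = jp$measure %||% "partnerwise",
                            min_duration = jp$min_duration %||% 5,
                            motion_floor = jp$motion_floor %||% 0.02,
                            smooth_k = jp$smooth_k %||% 1)
    emit("joints.csv", function(p)
      readr::write_csv(joints, p, progress = FALSE))
    stage <- "transitions"
    trans <- attribute_transitions(ts, ds,
                                   measure = jp$measure %||% "partnerwise",
                                   window = jp$window %||% 3,
                                   motion_floor = jp$motion_floor %||% 0.02,
                                   smooth_k = jp$smooth_k %||% 1)
    emit("transitions.csv", function(p)
      readr::write_csv(trans, p, progress = FALSE))
    emit("topography.json", function(p)
      write_topography_json(opposition_topography(trans), p))
    stage <- "contacts"
    contacts <- if (is.null(cfg$contacts)) {
      tibble::tibble()
    } else {
      cc <- cfg$contacts
      detect_contacts(ts, cfg$bm, actor = cc$actor,
                      recipient = cc$recipient,
                      actor_point = cc$actor_point %||% cfg$bm$midline[1],
                      tau_contact = cc$tau_contact %||% 0.10,
                      n_min = cc$n_min %||% 3,
                      merge_gap = cc$merge_gap %||% 2)
    }
    emit("contacts.csv", function(p)
      readr::write_csv(contacts, p, progress = FALSE))
    stage <- "score_sheet"
    sheet <- export_score_sheet(ds, stride = cfg$score_stride)
    emit("score_sheet.txt", function(p) write_score_sheet(sheet, p))
    stage <- "report"
    emit("report.md", function(p)
      write_report(p, cfg, ds, joints, trans, contacts))
    emit("manifest.json", function(p) write_manifest(p, cfg))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(stats::setNames(as.list(written), basename(written)))
}

write_report <- function(path, cfg, ds, joints, trans, contacts) {
  g <- glance(ds)
  lines <- c(
    "# Dyadic interaction report", "",
    sprintf("- input: `%s` (dialect %s)", cfg$input, cfg$dialect),
    sprintf("- frames: %d (%.1f%% with defined geometry)", g$n_frames,
            100 * g$prop_defined),
    sprintf("- reference lengths: %s",
            paste(names(ds$ref_lengths), round(ds$ref_lengths, 3),
                  sep = " = ", collapse = ", ")),
    sprintf("- mean relative distance: %.3f body lengths",
            g$mean_rel_distance),
    sprintf("- modal partnerwise sector: %s", g$modal_partnerwise),
    sprintf("- joints detected (%s): %d, of which dynamic: %d",
            cfg$joints$measure %||% "partnerwise", nrow(joints),
            sum(joints$dynamic)),
    sprintf("- transitions attributed: %d (focal %d / partner %d / both %d / ambiguous %d)",
            nrow(trans), sum(trans$attribution == "focal"),
            sum(trans$attribution == "partner"),
            sum(trans$attribution == "both"),
            sum(trans$attribution == "ambiguous")),
    sprintf("- contact events: %d", nrow(contacts)),
    "", "See manifest.json for the exact configuration."
  )
  writeLines(lines, path)
}

write_manifest <- function(path, cfg) {
  m <- list(
    package = "ewmnr",
    version = as.character(utils::packageVersion("ewmnr")),
    input = cfg$input,
    input_sha = unname(tools::md5sum(cfg$input)),
    config = cfg[setdiff(names(cfg), "bm")],
    body_model = list(midline = cfg$bm$midline,
                      region_bounds = as.list(cfg$bm$region_bounds),
                      tip_fraction = cfg$bm$tip_fraction,
                      heading = as.list(cfg$bm$heading),
                      n_segments = cfg$bm$n_segments)
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
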