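#' Synthetic dyads with ground truth
#'
#' Deterministic, seedable simulations of two interacting rigid-midline
#' agents, emitting both a noisy `track_set` (what a pose tracker would
#' produce) and the exact scripted ground truth (codes, movers, contact
#' targets) used as the oracle for every analysis module. Agents are
#' rigid midlines laid along their heading; flexion is not simulated —
#' sufficient to exercise every measure while keeping the truth exact.
#'
#' @name synth
NULL

#' Scenario specification
#'
#' Scenarios:
#' * `STATIC_ANTIPARALLEL` — two frozen anti-parallel bodies (the classic
#'   facing-past stand-off geometry; partnerwise sector 4 throughout).
#' * `CIRCLE_MAINTAIN` — both agents circle a common centre keeping the
#'   relative configuration locked (a dynamically maintained joint),
#'   interleaved with scripted single-mover in-place turns that switch
#'   the configuration (partnerwise 4 -> 6 -> 0 with the default frame
#'   count).
#' * `FPD_MUTUAL_BLOCK` — anti-parallel pair co-rotating in place so the
#'   configuration survives only through both animals' compensation.
#' * `BILL_TO_HEAD` — an attacker pure-pursuing a body target on a
#'   zigzag-evading defender, maintaining the opposition one-sidedly.
#' * `EVADE_ZIGZAG` — as above with a slower attacker: the defender's
#'   evasion wins and the configuration keeps changing.
#' * `APPROACH_CONTACT` — approach, touch a scripted target segment,
#'   optionally slide along the body, retreat.
#' * `RANDOM_WALK` — two independent correlated-heading random walkers.
#'
#' @param scenario scenario name (see above).
#' @param n_frames number of frames (>= 2). Default 500.
#' @param fps nominal frame rate (metadata).
#' @param n_keypoints keypoints per animal, 2..6 (default 4; 4-point
#'   bodies use the dorsal-landmark names `head`, `pronotum`,
#'   `mid_abdomen`, `abdomen_tip`).
#' @param body_length body length in arena units (default 10).
#' @param speed travel speed, body lengths/frame (default 0.05).
#' @param gains named controller gains `c(pursuer = , blocker = )` in
#'   `[0, 1]`; first-order heading relaxation toward the goal bearing.
#' @param target_segment contact target segment for `APPROACH_CONTACT`.
#' @param target_end optional end segment (contact slides from
#'   `target_segment` to `target_end` during the dwell).
#' @param noise_sd i.i.d. Gaussian keypoint noise, as a fraction of body
#'   length (default 0.005 = 0.5% body length).
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("STATIC_ANTIPARALLEL",
                                       "CIRCLE_MAINTAIN",
                                       "FPD_MUTUAL_BLOCK", "BILL_TO_HEAD",
                                       "EVADE_ZIGZAG", "APPROACH_CONTACT",
                                       "RANDOM_WALK"),
                          n_frames = 500, fps = 30, n_keypoints = 4,
                          body_length = 10, speed = 0.05,
                          gains = c(pursuer = 0.3, blocker = 0.5),
                          target_segment = 4, target_end = NULL,
                          noise_sd = 0.005, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_frames >= 2, n_keypoints >= 2, n_keypoints <= 6,
            body_length > 0, speed >= 0, noise_sd >= 0,
            all(gains >= 0 & gains <= 1))
  structure(list(scenario = scenario, n_frames = as.integer(n_frames),
                 fps = fps, n_keypoints = as.integer(n_keypoints),
                 body_length = body_length, speed = speed, gains = gains,
                 target_segment = as.integer(target_segment),
                 target_end = target_end, noise_sd = noise_sd,
                 seed = seed),
            class = "scenario_spec")
}

#' Body model matching a scenario's simulated animals
#' @param spec a [scenario_spec()].
#' @return a [body_model()].
#' @export
sim_body_model <- function(spec) {
  body_model(sim_bodyparts(spec$n_keypoints))
}

sim_bodyparts <- function(k) {
  if (k == 4) c("head", "pronotum", "mid_abdomen", "abdomen_tip")
  else paste0("kp", seq_len(k))
}

#' Simulate a scenario
#'
#' @param spec a [scenario_spec()].
#' @return a `dyad_sim`: list with
#'   * `tracks` — noisy `track_set` (animals `"a"` and `"b"`);
#'   * `truth` — list of tibbles: `frames` (`frame`, `partnerwise`,
#'     `opposition`, `contact`, `target_segment`, `moved_a`, `moved_b`),
#'     `transitions` (`frame`, `from`, `to`, `mover`), and `meta`;
#'   * `spec` — the input spec.
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  run <- function() {
    script <- switch(spec$scenario,
                     STATIC_ANTIPARALLEL = script_static(spec),
                     CIRCLE_MAINTAIN = script_circle(spec),
                     FPD_MUTUAL_BLOCK = script_fpd(spec),
                     BILL_TO_HEAD = script_track_target(spec),
                     EVADE_ZIGZAG = script_pursuit(spec),
                     APPROACH_CONTACT = script_contact(spec),
                     RANDOM_WALK = script_random_walk(spec),
                     stop("unknown scenario: ", spec$scenario,
                          call. = FALSE))
    assemble_sim(spec, script)
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

# rigid keypoints [T, K, 2] from centroids [T,2] and headings [T]
rigid_keypoints <- function(cent, theta, L, K) {
  u <- unit_cw(theta)
  offs <- L / 2 - (seq_len(K) - 1) * L / (K - 1)
  arr <- array(NA_real_, c(nrow(cent), K, 2))
  for (j in seq_len(K)) {
    arr[, j, 1] <- cent[, 1] + offs[j] * u[, 1]
    arr[, j, 2] <- cent[, 2] + offs[j] * u[, 2]
  }
  arr
}

assemble_sim <- function(spec, script) {
  t_n <- spec$n_frames
  K <- spec$n_keypoints
  L <- spec$body_length
  parts <- sim_bodyparts(K)
  bm <- sim_body_model(spec)
  kp_a <- rigid_keypoints(script$cent_a, script$th_a, L, K)
  kp_b <- rigid_keypoints(script$cent_b, script$th_b, L, K)

  # scripted per-frame truth (noise-free)
  pw <- sectorize(wrap360(script$th_b - script$th_a), 8)
  opp <- character(t_n)
  for (i in seq_len(t_n)) {
    pa <- matrix(kp_a[i, , ], K, 2, dimnames = list(parts, c("x", "y")))
    pb <- matrix(kp_b[i, , ], K, 2, dimnames = list(parts, c("x", "y")))
    o <- opposition_core(midline_polyline(pa, bm), midline_polyline(pb, bm),
                         bm)
    opp[i] <- paste0(o$opp_focal, "/", o$opp_partner)
  }
  moved <- function(cent, th) {
    c(FALSE, sqrt(rowSums(diff(cent)^2)) > 1e-9 * L |
        abs(wrap180(diff(th))) > 1e-9)
  }
  moved_a <- moved(script$cent_a, script$th_a)
  moved_b <- moved(script$cent_b, script$th_b)
  contact <- script$contact %||% rep(FALSE, t_n)
  target_segment <- script$target_segment %||% rep(NA_integer_, t_n)

  frames <- tibble::tibble(
    frame = 0:(t_n - 1L), partnerwise = pw, opposition = opp,
    contact = contact, target_segment = target_segment,
    moved_a = moved_a, moved_b = moved_b
  )
  chg <- which(pw[-1] != pw[-t_n])
  transitions <- tibble::tibble(
    frame = as.integer(chg),             # 0-based frame of the new code
    from = pw[chg], to = pw[chg + 1L],
    mover = dplyr::case_when(
      moved_a[chg + 1L] & moved_b[chg + 1L] ~ "both",
      moved_a[chg + 1L] ~ "a",
      moved_b[chg + 1L] ~ "b",
      TRUE ~ "none"
    )
  )

  noise <- function(kp) {
    kp + stats::rnorm(length(kp), sd = spec$noise_sd * L)
  }
  kp_a_n <- noise(kp_a)
  kp_b_n <- noise(kp_b)
  long <- function(kp, who) {
    tibble::tibble(
      frame = rep(0:(t_n - 1L), times = K),
      animal = who,
      bodypart = rep(parts, each = t_n),
      x = as.vector(kp[, , 1]), y = as.vector(kp[, , 2]),
      confidence = 1
    )
  }
  tracks <- as_track_set(dplyr::bind_rows(long(kp_a_n, "a"),
                                          long(kp_b_n, "b")),
                         fps = spec$fps, arena_units = "au")
  structure(
    list(tracks = tracks,
         truth = list(frames = frames, transitions = transitions,
                      meta = c(script$meta,
                               list(scenario = spec$scenario,
                                    body_length = L))),
         spec = spec),
    class = "dyad_sim"
  )
}

#' @export
print.dyad_sim <- function(x, ...) {
  cat(sprintf("<dyad_sim> %s: %d frames, noise %.3g BL, seed %s\n",
              x$spec$scenario, x$spec$n_frames, x$spec$noise_sd,
              format(x$spec$seed)))
  invisible(x)
}

# --- scenario scripts ----------------------------------------------------

script_static <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  list(cent_a = matrix(c(0, 0), t_n, 2, byrow = TRUE),
       cent_b = matrix(c(1.0 * L, 0), t_n, 2, byrow = TRUE),
       th_a = rep(0, t_n), th_b = rep(180, t_n))
}

# circling with locked configuration, punctuated by single-mover turns
script_circle <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  R <- 1.25 * L
  v <- spec$speed * L
  omega <- 2 * asin(min(1, v / (2 * R))) * 180 / pi   # chord-exact step
  # 90-degree in-place turns, eased at both ends so sector crossings land
  # mid-bin, preceded by a short hold so attribution windows never mix
  # turning with circling
  ramp <- c(7.5, rep(15, 5), 7.5)
  hold_len <- 3L
  turn_len <- length(ramp) + hold_len
  t1 <- max(2L, floor(0.30 * t_n))
  t2 <- max(t1 + turn_len + 2L, floor(0.64 * t_n))
  delta0 <- 10                                         # breaks parallelism

  phi <- numeric(t_n); delta <- numeric(t_n); alpha <- numeric(t_n)
  delta[1] <- delta0
  turn_step <- function(f, ts) {
    k <- f - ts - hold_len
    if (k >= 0 && k < length(ramp)) ramp[k + 1] else 0
  }
  for (i in 2:t_n) {
    f <- i - 1L                                        # 0-based frame
    in_turn_b <- f >= t1 && f < t1 + turn_len && t1 + turn_len <= t_n
    in_turn_a <- f >= t2 && f < t2 + turn_len && t2 + turn_len <= t_n
    phi[i] <- phi[i - 1] + if (in_turn_b || in_turn_a) 0 else omega
    delta[i] <- delta[i - 1] + if (in_turn_b) turn_step(f, t1) else 0
    alpha[i] <- alpha[i - 1] - if (in_turn_a) turn_step(f, t2) else 0
  }
  rphi <- phi * pi / 180
  cent_a <- R * cbind(sin(rphi), cos(rphi))
  cent_b <- -cent_a
  list(cent_a = cent_a, cent_b = cent_b,
       th_a = wrap360(phi + 90 + alpha),
       th_b = wrap360(phi + 270 + delta),
       meta = list(joint_phases = list(c(0L, t1), c(t1 + turn_len, t2),
                                       c(t2 + turn_len, t_n)),
                   turns = tibble::tibble(
                     start = c(t1, t2), end = c(t1, t2) + turn_len,
                     mover = c("b", "a"))))
}

# anti-parallel pair co-rotating in place: mutual compensation
script_fpd <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  osc <- 40 * sin(2 * pi * (0:(t_n - 1)) / 50)
  list(cent_a = matrix(c(0, 0), t_n, 2, byrow = TRUE),
       cent_b = matrix(c(1.0 * L, 0), t_n, 2, byrow = TRUE),
       th_a = wrap360(osc), th_b = wrap360(180 + osc))
}

# one-sided maintenance: the defender swings its heading in place trying
# to face away/around; the attacker shadows the defender's rear target
# with a short reaction lag, keeping a front-to-rear opposition that only
# the attacker's movement preserves
script_track_target <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  lag <- 3L
  amp <- 60
  period <- 80
  psi <- amp * sin(2 * pi * (0:(t_n - 1)) / period)
  psi_lag <- psi[pmax(1, seq_len(t_n) - lag)]
  u <- unit_cw(psi)
  ul <- unit_cw(psi_lag)
  list(cent_a = -1.25 * L * ul,          # attacker, station behind the rear
       cent_b = matrix(0, t_n, 2),       # defender rotates in place
       th_a = wrap360(psi_lag), th_b = wrap360(psi))
}

# defender zigzag-flees; a slower attacker pure-pursues its rear target
# point: the defender escapes and the configuration keeps changing
script_pursuit <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  v_b <- spec$speed * L
  v_a <- 0.6 * v_b
  g <- spec$gains[["pursuer"]]
  amp <- 70
  turn_cap <- 8                         # deg/frame defender heading slew
  cent_a <- matrix(NA_real_, t_n, 2)
  cent_b <- matrix(NA_real_, t_n, 2)
  th_a <- numeric(t_n); th_b <- numeric(t_n)
  cent_b[1, ] <- c(0, 0); th_b[1] <- 0
  cent_a[1, ] <- c(0, -1.3 * L); th_a[1] <- 0
  for (i in 2:t_n) {
    f <- i - 1L
    goal_b <- amp * ifelse((f %/% 25) %% 2 == 0, 1, -1)
    err <- wrap180(goal_b - th_b[i - 1])
    th_b[i] <- wrap360(th_b[i - 1] + pmin(turn_cap, pmax(-turn_cap, err)))
    cent_b[i, ] <- cent_b[i - 1, ] + v_b * unit_cw(th_b[i])
    tail_b <- cent_b[i - 1, ] - (L / 2) * as.numeric(unit_cw(th_b[i - 1]))
    d <- tail_b - cent_a[i - 1, ]
    goal_a <- bearing_cw(d[1], d[2])
    th_a[i] <- wrap360(th_a[i - 1] + g * wrap180(goal_a - th_a[i - 1]))
    gap_now <- sqrt(sum(d^2))
    adv <- min(v_a, max(0, gap_now - 0.8 * L))   # keep station, no overrun
    cent_a[i, ] <- cent_a[i - 1, ] + adv * as.numeric(unit_cw(th_a[i]))
  }
  list(cent_a = cent_a, cent_b = cent_b, th_a = th_a, th_b = th_b)
}

# approach a scripted target segment on a static recipient, dwell
# (optionally sliding to target_end), retreat
script_contact <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  v <- spec$speed * L
  nseg <- 4L
  s <- spec$target_segment
  s_end <- spec$target_end %||% s
  yt <- function(seg) L / 2 - (seg - 0.5) / nseg * L
  dwell <- 12L
  touch_x <- 0.03 * L
  start_x <- 1.2 * L
  cent_a <- matrix(NA_real_, t_n, 2)
  th_a <- numeric(t_n)
  contact <- logical(t_n)
  # head leads at +L/2 along heading; heading 270 points -x
  cent_a[1, ] <- c(start_x + L / 2, yt(s)); th_a[1] <- 270
  phase <- "approach"; dwelt <- 0L
  for (i in 2:t_n) {
    prev <- cent_a[i - 1, ]
    head_x <- prev[1] - L / 2
    if (phase == "approach" && head_x <= touch_x) phase <- "dwell"
    if (phase == "dwell" && dwelt >= dwell) phase <- "retreat"
    if (phase == "approach") {
      th_a[i] <- 270
      cent_a[i, ] <- prev + c(-min(v, max(0, head_x - touch_x)), 0)
    } else if (phase == "dwell") {
      dwelt <- dwelt + 1L
      th_a[i] <- 270
      yy <- yt(s) + (yt(s_end) - yt(s)) * dwelt / dwell
      cent_a[i, ] <- c(prev[1], yy)
    } else {
      th_a[i] <- 90
      cent_a[i, ] <- prev + c(v, 0)
    }
  }
  head_x <- cent_a[, 1] - L / 2
  contact <- head_x <= 0.10 * L & abs(cent_a[, 2]) <= L / 2
  list(cent_a = cent_a,
       cent_b = matrix(c(0, 0), t_n, 2, byrow = TRUE),
       th_a = th_a, th_b = rep(0, t_n),
       contact = contact,
       target_segment = ifelse(contact, s, NA_integer_),
       meta = list(target_segment = s, target_end = s_end))
}

script_random_walk <- function(spec) {
  t_n <- spec$n_frames; L <- spec$body_length
  v <- spec$speed * L
  walk <- function(x0, th0) {
    th <- wrap360(th0 + cumsum(c(0, stats::rnorm(t_n - 1, sd = 15))))
    u <- unit_cw(th)
    cent <- cbind(x0[1] + cumsum(c(0, v * u[-1, 1])),
                  x0[2] + cumsum(c(0, v * u[-1, 2])))
    list(cent = cent, th = th)
  }
  a <- walk(c(0, 0), stats::runif(1, 0, 360))
  b <- walk(c(2 * L, 0), stats::runif(1, 0, 360))
  list(cent_a = a$cent, cent_b = b$cent, th_a = a$th, th_b = b$th)
}

#' Randomly mask detections (tracking-dropout post-step)
#'
#' @param ts a `track_set`.
#' @param rate per-point dropout probability.
#' @param seed integer seed for the masking (independent of the
#'   simulation seed).
#' @return a `track_set` with masked points set missing and confidence 0.
#' @export
mask_dropouts <- function(ts, rate, seed = 1) {
  df <- tibble::as_tibble(ts)
  drop <- withr::with_seed(seed, stats::runif(nrow(df)) < rate)
  df$x[drop] <- NA_real_
  df$y[drop] <- NA_real_
  df$confidence[drop] <- 0
  new_track_set(df, fps = attr(ts, "fps"),
                arena_units = attr(ts, "arena_units"))
}
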