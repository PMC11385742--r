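# Scripted-turn circling scenario: three long locked phases separated by
# single-mover turns; used throughout as the canonical joint substrate.
circle_sim <- function(seed = 3, n_frames = 500, noise_sd = 0.005) {
  simulate_scenario(scenario_spec("CIRCLE_MAINTAIN", n_frames = n_frames,
                                  noise_sd = noise_sd, seed = seed))
}

test_that("scripted joints are recovered as maximal constant runs", {
  sim <- circle_sim()
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  joints <- detect_joints(ds, min_duration = 5)
  tj <- truth_joints(sim, min_duration = 5)
  expect_equal(nrow(tj), 3)
  al <- truth_alignment(sim, joints = joints)
  expect_true(all(al$joints$jaccard >= 0.9))
  expect_true(all(joints$dynamic))
  # intervals are disjoint and sorted
  expect_true(all(diff(joints$start) > 0))
  expect_true(all(joints$start[-1] >= joints$end[-nrow(joints)]))
  # consecutive joints carry different codes
  expect_true(all(joints$code[-1] != joints$code[-nrow(joints)]))
})

test_that("frozen animals give a static posture, not an attractor", {
  sim <- simulate_scenario(scenario_spec("STATIC_ANTIPARALLEL",
                                         n_frames = 80, noise_sd = 0,
                                         seed = 1))
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  j <- detect_joints(ds, min_duration = 10)
  expect_equal(nrow(j), 1)
  expect_false(j$dynamic)
  expect_equal(j$maintainer, "static")
  expect_true(is.na(j$ci))
})

test_that("random walks hold configurations for shorter than circling", {
  mean_dur <- function(scenario) {
    durs <- vapply(1:5, function(s) {
      sim <- simulate_scenario(scenario_spec(scenario, n_frames = 300,
                                             noise_sd = 0.005, seed = s))
      ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
      j <- detect_joints(ds, min_duration = 2)
      if (nrow(j) == 0) 0 else mean(j$duration)
    }, numeric(1))
    mean(durs)
  }
  expect_gt(mean_dur("CIRCLE_MAINTAIN"), mean_dur("RANDOM_WALK"))
})

test_that("mirrored pursuit has ci 1; a lone mover has ci 0", {
  # noise-free circling: the relational state is exactly constant while
  # both animals move every frame
  sim <- circle_sim(seed = 5, noise_sd = 0)
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  expect_equal(compensation_index(ds, 10, 140), 1)

  # one animal rotates in place, the other frozen: all motion shows up
  # relationally
  t_n <- 60
  th_b <- seq(0, 118, by = 2)
  ts <- rigid_dyad_tracks(matrix(0, t_n, 2), rep(90, t_n),
                          matrix(rep(c(25, 0), each = t_n), t_n, 2), th_b)
  ds1 <- relational_series(ts, default_bm())
  expect_equal(compensation_index(ds1, 0, t_n), 0)
})

test_that("ci degrades as independent noise is added to one animal", {
  cis <- vapply(c(0, 0.01, 0.03), function(sd) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_scenario(scenario_spec("CIRCLE_MAINTAIN",
                                             n_frames = 200,
                                             noise_sd = sd, seed = s))
      ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
      compensation_index(ds, 10, 140)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("ci is invariant under rigid motion and scaling", {
  sim <- circle_sim(seed = 7, n_frames = 200)
  bm <- sim_body_model(sim$spec)
  ds <- relational_series(sim$tracks, bm)
  ci0 <- compensation_index(ds, 10, 140)
  ts_t <- transform_tracks(sim$tracks, angle = 123, shift = c(40, -7),
                           scale = 3.7)
  ci1 <- compensation_index(relational_series(ts_t, bm), 10, 140)
  expect_equal(ci1, ci0, tolerance = 1e-9)
})

test_that("single-mover transitions are attributed to the mover", {
  sim <- circle_sim(seed = 11)
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  trans <- attribute_transitions(sim$tracks, ds, window = 3)
  al <- truth_alignment(sim, transitions = trans)
  expect_true(all(al$transitions$detected))
  expect_true(all(al$transitions$correct))
  expect_error(attribute_transition(sim$tracks, ds, t = 1, window = 3),
               "before the first frame")
})

test_that("co-produced transitions are attributed to both", {
  # both animals rotate at once (opposite senses) into a new mutual facing
  th_a <- c(rep(0, 10), rep(30, 10))
  th_b <- 180 - th_a
  t_n <- length(th_a)
  ts <- rigid_dyad_tracks(matrix(0, t_n, 2), th_a,
                          matrix(rep(c(25, 0), each = t_n), t_n, 2), th_b)
  ds <- relational_series(ts, default_bm())
  trans <- attribute_transitions(ts, ds, window = 4)
  expect_gt(nrow(trans), 0)
  expect_true(all(trans$attribution == "both"))
})

test_that("sub-floor jitter flips are ambiguous", {
  # the relative heading sits on a sector boundary and creeps across it
  th_b <- 180 + seq(22.4, 22.7, length.out = 12)
  t_n <- length(th_b)
  ts <- rigid_dyad_tracks(matrix(0, t_n, 2), rep(0, t_n),
                          matrix(rep(c(25, 0), each = t_n), t_n, 2), th_b)
  ds <- relational_series(ts, default_bm())
  trans <- attribute_transitions(ts, ds, window = 3)
  expect_gt(nrow(trans), 0)
  expect_true(all(trans$attribution == "ambiguous"))
})

test_that("attribution equals exhaustive evaluation of the freezes", {
  # independent oracle: enumerate the four freeze combinations from the
  # scripted headings, discretize by hand, and apply the decision rule
  oracle <- function(ha0, ha1, hb0, hb1, w = 45) {
    sec <- function(hf, hp) floor((((hp - hf) %% 360) / w) + 0.5) %% 8
    from <- sec(ha0, hb0); to <- sec(ha1, hb1)
    cf_f <- sec(ha1, hb0); cf_p <- sec(ha0, hb1)
    if (from == to) return(NA_character_)
    if (cf_f == to && cf_p == to) "both"
    else if (cf_f == to && cf_p == from) "focal"
    else if (cf_p == to && cf_f == from) "partner"
    else "ambiguous"
  }
  set.seed(19)
  n_checked <- 0
  for (i in 1:40) {
    ha <- runif(2, 0, 360); hb <- runif(2, 0, 360)
    th_a <- c(rep(ha[1], 4), rep(ha[2], 4))
    th_b <- c(rep(hb[1], 4), rep(hb[2], 4))
    ts <- rigid_dyad_tracks(matrix(0, 8, 2), th_a,
                            matrix(rep(c(25, 0), each = 8), 8, 2), th_b)
    ds <- relational_series(ts, default_bm())
    exp_att <- oracle(ha[1], ha[2], hb[1], hb[2])
    if (is.na(exp_att)) next
    got <- attribute_transition(ts, ds, t = 4, window = 2,
                                motion_floor = 0)
    expect_equal(got$attribution, exp_att)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("maintenance classification separates mutual from one-sided", {
  # mutually blocked stand-off: both co-rotate, both necessary
  sim <- simulate_scenario(scenario_spec("FPD_MUTUAL_BLOCK",
                                         n_frames = 200,
                                         noise_sd = 0.002, seed = 4))
  bm <- sim_body_model(sim$spec)
  ds <- relational_series(sim$tracks, bm)
  j <- detect_joints(ds, min_duration = 50)
  m <- classify_maintenance(sim$tracks, ds, j$start[1], j$end[1],
                            window = 10)
  expect_equal(m$maintainer, "mutual")
  expect_gt(m$necessity_focal, 0.25)
  expect_gt(m$necessity_partner, 0.25)

  # attacker tracking an evading defender's body target: one-sided
  sim2 <- simulate_scenario(scenario_spec("BILL_TO_HEAD", n_frames = 300,
                                          noise_sd = 0.002, seed = 4))
  ds2 <- relational_series(sim2$tracks, bm)
  j2 <- detect_joints(ds2, measure = "opposition", min_duration = 100)
  expect_gt(nrow(j2), 0)
  m2 <- classify_maintenance(sim2$tracks, ds2, j2$start[1], j2$end[1],
                             window = 6, measure = "opposition")
  expect_equal(m2$maintainer, "focal")
  expect_lt(m2$necessity_partner, 0.25)

  # neither animal ever threatens the code: static
  sim3 <- simulate_scenario(scenario_spec("STATIC_ANTIPARALLEL",
                                          n_frames = 100, noise_sd = 0,
                                          seed = 2))
  ds3 <- relational_series(sim3$tracks, sim_body_model(sim3$spec))
  m3 <- classify_maintenance(sim3$tracks, ds3, 0, 100, window = 6)
  expect_equal(m3$maintainer, "static")
  expect_error(classify_maintenance(sim3$tracks, ds3, 0, 4, window = 6),
               "shorter than")
})

test_that("joints plus transitions reconstruct the code sequence", {
  sim <- circle_sim(seed = 13)
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  codes <- ewmnr:::code_series(ds, "partnerwise")
  joints <- detect_joints(ds, min_duration = 5)
  for (i in seq_len(nrow(joints))) {
    run <- codes[(joints$start[i] + 1):joints$end[i]]
    expect_true(all(run == joints$code[i]))
  }
  trans <- attribute_transitions(sim$tracks, ds, window = 3)
  # every code change is either inside a short unclaimed stretch or at a
  # reported transition frame
  chg <- which(codes[-1] != codes[-length(codes)])
  expect_true(all(chg %in% trans$frame))
})
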