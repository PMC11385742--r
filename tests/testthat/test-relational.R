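test_that("partnerwise reproduces the anti-parallel worked example", {
  # focal faces up-page, partner faces down-page -> sector 4
  expect_identical(partnerwise(90, 270)$partnerwise, 4L)
  expect_identical(partnerwise(0, 180)$partnerwise, 4L)
  expect_identical(partnerwise(123.4, 123.4)$partnerwise, 0L)
})

test_that("partnerwise sectors are antisymmetric mod 8", {
  # brute force over all 8 sector centres (and 16)
  for (n in c(8L, 16L)) {
    w <- 360 / n
    for (k in 0:(n - 1)) {
      s1 <- partnerwise(0, k * w, n)$partnerwise
      s2 <- partnerwise(k * w, 0, n)$partnerwise
      expect_identical(as.integer((s1 + s2) %% n), 0L)
      expect_identical(s1, as.integer(k))
    }
  }
  # rel_heading antisymmetry on arbitrary headings
  set.seed(3)
  h <- matrix(runif(40, 0, 360), ncol = 2)
  r1 <- partnerwise(h[, 1], h[, 2])$rel_heading
  r2 <- partnerwise(h[, 2], h[, 1])$rel_heading
  expect_true(all((r1 + r2) %% 360 < 1e-9 | abs((r1 + r2) %% 360 - 360) < 1e-9))
})

test_that("nose-to-nose opposition is bill-to-bill and 2H/2H works", {
  bm4 <- default_bm()
  # two animals on a line, facing each other, 2 units apart
  up <- rigid_pose_rows(0, "a", c(0, 0), 0, L = 10)
  down <- rigid_pose_rows(0, "b", c(0, 12), 180, L = 10)
  pa <- midline_polyline(up, bm4)
  pb <- midline_polyline(down, bm4)
  o <- opposition(pa, pb, bm4)
  expect_equal(o$opp_focal, "0")
  expect_equal(o$opp_partner, "0")
  expect_equal(o$gap, 2)

  # anti-parallel side-by-side, slightly head-offset: right head sides oppose
  a <- rigid_pose_rows(0, "a", c(0, 0.3), 0, L = 10)
  b <- rigid_pose_rows(0, "b", c(2, 0.5), 180, L = 10)
  o2 <- opposition(midline_polyline(a, bm4), midline_polyline(b, bm4), bm4)
  expect_equal(substr(o2$opp_focal, 1, 1), "2")
  expect_equal(substr(o2$opp_partner, 1, 1), "2")
})

test_that("closest-pair gap matches the dense-sampling oracle", {
  set.seed(13)
  for (i in 1:50) {
    p1 <- poly_from_pts(random_polyline_pts(4))
    p2 <- poly_from_pts(random_polyline_pts(4))
    fast <- closest_pair_polylines(p1, p2)
    slow <- brute_closest_pair(p1, p2, n = 500)
    spacing <- max(p1$length, p2$length) / 499
    expect_lt(abs(fast$gap - slow), spacing)
  }
})

test_that("relative distance is gap over reference length", {
  expect_equal(relative_distance(20, 10), 2)
  expect_equal(relative_distance(0, 10), 0)
  expect_equal(relative_distance(10, 10) / 2, relative_distance(5, 10))
  expect_error(relative_distance(5, 0), "positive")
})

test_that("weight codes follow the egocentric step convention", {
  bm4 <- default_bm()
  # heading up, stepping to own left -> S[6]; oblique left rear -> S[5]
  mk <- function(step) {
    rigid_dyad_tracks(rbind(c(0, 0), c(0, 0) + step),
                      th_a = c(0, 0),
                      cent_b = rbind(c(30, 0), c(30, 0)),
                      th_b = c(0, 0))
  }
  k_left <- kinematics(mk(c(-2, 0)), "a", bm4)
  expect_identical(k_left$weight_code[2], 6L)
  k_lr <- kinematics(mk(c(-2, -2)), "a", bm4)
  expect_identical(k_lr$weight_code[2], 5L)
  k_right <- kinematics(mk(c(2, 0)), "a", bm4)
  expect_identical(k_right$weight_code[2], 2L)
  # zero displacement: no weight code, zero magnitude
  k0 <- kinematics(mk(c(0, 0)), "a", bm4)
  expect_true(is.na(k0$weight_code[2]))
  expect_equal(k0$step_mag[2], 0)
  # sub-floor jitter suppressed
  kj <- kinematics(mk(c(0.1, 0)), "a", bm4, step_floor = 0.02)
  expect_true(is.na(kj$weight_code[2]))
})

test_that("d_heading integrates to total rotation on rigid motion", {
  set.seed(17)
  t_n <- 50
  dth <- runif(t_n - 1, -30, 30)
  th <- cumsum(c(20, dth))
  cent <- cbind(seq_len(t_n) * 0.1, 0)
  ts <- rigid_dyad_tracks(cent, th, cent + 30, rep(0, t_n))
  k <- kinematics(ts, "a", default_bm())
  expect_equal(sum(k$d_heading[-1]), th[t_n] - th[1], tolerance = 1e-9)
  expect_true(all(abs(k$d_heading[-1]) <= 180))
})

test_that("relational_series output is structurally complete", {
  sim <- simulate_scenario(scenario_spec("RANDOM_WALK", n_frames = 40,
                                         seed = 23))
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  expect_s3_class(ds, "dyad_series")
  expect_equal(nrow(ds$measures), 40 * 2)   # T x ordered pairs
  expect_equal(nrow(ds$kinematics), 40 * 2)
  # swap properties: sectors sum to 0 mod 8, gap swap-invariant,
  # opposition codes swap positions
  ma <- ds$measures[ds$measures$focal == "a", ]
  mb <- ds$measures[ds$measures$focal == "b", ]
  ok <- ma$defined & mb$defined
  expect_true(all((ma$partnerwise[ok] + mb$partnerwise[ok]) %% 8 == 0))
  expect_equal(ma$gap, mb$gap)
  expect_equal(ma$contact, mb$contact)
  expect_equal(ma$opp_focal, mb$opp_partner)
  expect_equal(ma$opp_partner, mb$opp_focal)
  expect_error(relational_series(
    as_track_set(data.frame(frame = 0, animal = "solo", bodypart = "head",
                            x = 0, y = 0)), default_bm()),
    "exactly 2")
})

test_that("undefined frames are flagged, not dropped", {
  sim <- simulate_scenario(scenario_spec("RANDOM_WALK", n_frames = 20,
                                         seed = 29))
  df <- tibble::as_tibble(sim$tracks)
  df$x[df$frame %in% 5:6 & df$animal == "a"] <- NA
  df$y[df$frame %in% 5:6 & df$animal == "a"] <- NA
  ds <- relational_series(as_track_set(df), sim_body_model(sim$spec))
  ma <- ds$measures[ds$measures$focal == "a", ]
  expect_equal(nrow(ma), 20)
  expect_false(any(ma$defined[ma$frame %in% 5:6]))
  expect_true(all(ma$defined[!ma$frame %in% 5:6]))
})

test_that("all relational measures survive rigid motion and scaling", {
  set.seed(37)
  sim <- simulate_scenario(scenario_spec("RANDOM_WALK", n_frames = 30,
                                         seed = 37))
  bm4 <- sim_body_model(sim$spec)
  ds0 <- relational_series(sim$tracks, bm4)
  for (i in 1:3) {
    ts_t <- transform_tracks(sim$tracks, angle = runif(1, 0, 360),
                             shift = runif(2, -100, 100),
                             scale = runif(1, 0.1, 8))
    ds_t <- relational_series(ts_t, bm4)
    expect_identical(ds_t$measures$partnerwise, ds0$measures$partnerwise)
    expect_identical(ds_t$measures$opposition, ds0$measures$opposition)
    expect_equal(ds_t$measures$rel_heading, ds0$measures$rel_heading,
                 tolerance = 1e-9)
    expect_equal(ds_t$measures$rel_distance, ds0$measures$rel_distance,
                 tolerance = 1e-9)
    expect_identical(ds_t$kinematics$weight_code,
                     ds0$kinematics$weight_code)
    expect_equal(ds_t$kinematics$step_mag, ds0$kinematics$step_mag,
                 tolerance = 1e-9)
  }
})

test_that("score sheet compresses runs and round-trips change points", {
  sim <- simulate_scenario(scenario_spec("STATIC_ANTIPARALLEL",
                                         n_frames = 30, noise_sd = 0,
                                         seed = 1))
  ds <- relational_series(sim$tracks, sim_body_model(sim$spec))
  sheet <- export_score_sheet(ds)
  # constant series: single entry per row
  expect_true(all(table(sheet$row) == 1))
  expect_equal(sheet$value[sheet$row == "partnerwise"], "4")

  sim2 <- simulate_scenario(scenario_spec("CIRCLE_MAINTAIN",
                                          n_frames = 200, noise_sd = 0,
                                          seed = 2))
  ds2 <- relational_series(sim2$tracks, sim_body_model(sim2$spec))
  sheet2 <- export_score_sheet(ds2, stride = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_score_sheet(sheet2, f)
  back <- parse_score_sheet(f)
  expect_equal(back$frame, sheet2$frame)
  expect_equal(back$value, sheet2$value)
  expect_equal(back$row, as.character(sheet2$row))
})

test_that("a scripted approach shows a distance decrease on the sheet", {
  # both animals step laterally (one left, one right) while the gap
  # closes by half a body length
  L <- 10
  t_n <- 21
  xa <- seq(0, 9, length.out = t_n)          # a steps to its right
  xb <- seq(17, 21, length.out = t_n)        # b (facing down) to its left
  ts <- rigid_dyad_tracks(cbind(xa, 0), rep(0, t_n),
                          cbind(xb, 0), rep(180, t_n), L = L)
  ds <- relational_series(ts, default_bm())
  sheet <- export_score_sheet(ds)
  dist_cells <- as.numeric(sheet$value[sheet$row == "distance"])
  expect_equal(dist_cells[1] - dist_cells[length(dist_cells)], 0.5)
  # weight rows show the two lateral steps: a right (2), b left (6)
  expect_true("2" %in% sheet$value[sheet$row == "Weight(a)"])
  expect_true("6" %in% sheet$value[sheet$row == "Weight(b)"])
})
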