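write_dlc_csv <- function(path, animals = c("ind1", "ind2"),
                          parts = c("head", "pronotum", "mid_abdomen",
                                    "abdomen_tip"),
                          n = 100, drop_coords_row = FALSE,
                          duplicate_part = FALSE) {
  cols <- expand.grid(coord = c("x", "y", "likelihood"), part = parts,
                      ind = animals, stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$ind, animals), match(cols$part, parts)), ]
  if (duplicate_part) cols <- rbind(cols, cols[1:3, ])
  hdr <- rbind(
    c("scorer", rep("DLC_resnet", nrow(cols))),
    c("individuals", cols$ind),
    c("bodyparts", cols$part),
    c("coords", cols$coord)
  )
  if (drop_coords_row) hdr <- hdr[1:3, ]
  set.seed(42)
  vals <- matrix(round(runif(n * nrow(cols), 0, 640), 3), nrow = n)
  vals[, which(cols$coord == "likelihood")] <- 0.99
  body <- cbind(seq_len(n) - 1L, vals)
  con <- file(path, "w")
  on.exit(close(con))
  apply(hdr, 1, function(r) writeLines(paste(r, collapse = ","), con))
  apply(body, 1, function(r) writeLines(paste(r, collapse = ","), con))
  invisible(path)
}

test_that("multi-animal DLC CSV round-trips structurally", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(f, n = 100)
  ts <- read_dlc_tracks(f, "multi_animal_csv")
  expect_s3_class(ts, "track_set")
  expect_equal(length(animals(ts)), 2)
  expect_equal(sort(bodyparts(ts)),
               sort(c("head", "pronotum", "mid_abdomen", "abdomen_tip")))
  expect_equal(n_frames(ts), 100)
  expect_equal(nrow(ts), 100 * 2 * 4)
  # likelihood mapped to confidence
  expect_true(all(ts$confidence == 0.99))
  # image coords: y flipped by default for pixel data
  ts_math <- read_dlc_tracks(f, "multi_animal_csv", image_coords = FALSE)
  expect_equal(ts$y, -ts_math$y)
})

test_that("four dorsal landmarks per animal survive parsing", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(f, n = 10)
  ts <- read_dlc_tracks(f, "multi_animal_csv")
  per_animal <- table(unique(ts[, c("animal", "bodypart")])$animal)
  expect_true(all(per_animal == 4))
})

test_that("malformed DLC headers are format errors naming the level", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(f, n = 5, drop_coords_row = TRUE)
  expect_error(read_dlc_tracks(f, "multi_animal_csv"), "coords")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(f2, n = 5, duplicate_part = TRUE)
  expect_error(read_dlc_tracks(f2, "multi_animal_csv"), "duplicated")
  expect_error(read_dlc_tracks(f, "hdf5"), "format error")
})

test_that("tidy tracks round-trip exactly and default confidence to 1", {
  df <- expand.grid(frame = 0:4, animal = c("a", "b"),
                    bodypart = c("head", "tail"),
                    stringsAsFactors = FALSE)
  set.seed(7)
  df$x <- runif(nrow(df))
  df$y <- runif(nrow(df))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, f)
  ts <- read_tidy_tracks(f)
  expect_true(all(ts$confidence == 1))   # absent column defaults to 1

  # write/read round trip is bit-exact for non-missing points
  ts0 <- as_track_set(df)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tidy_tracks(ts0, f2)
  ts2 <- read_tidy_tracks(f2)
  expect_identical(ts2$x, ts0$x)
  expect_identical(ts2$y, ts0$y)
  expect_equal(tibble::as_tibble(ts2), tibble::as_tibble(ts0))
})

test_that("single-frame tidy table and missing combinations work", {
  df <- data.frame(frame = 0, animal = rep(c("a", "b"), each = 3),
                   bodypart = rep(c("p1", "p2", "p3"), 2),
                   x = 1:6, y = 1:6)
  ts <- as_track_set(df)
  expect_equal(n_frames(ts), 1)
  # a missing combination becomes a missing point, not a missing row
  df2 <- df[-2, ]
  ts2 <- as_track_set(df2)
  expect_equal(nrow(ts2), 6)
  expect_true(is.na(ts2$x[ts2$animal == "a" & ts2$bodypart == "p2"]))
})

test_that("tidy reader rejects missing columns and bad coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(frame = 0, animal = "a", x = 1, y = 2), f)
  expect_error(read_tidy_tracks(f), "bodypart")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(frame = 0, animal = "a", bodypart = "h",
                              x = "oops", y = "nope"), f2)
  expect_error(read_tidy_tracks(f2), "non-numeric")
})

test_that("gap interpolation follows the max_gap rule", {
  df <- data.frame(frame = 0:6, animal = "a", bodypart = "head",
                   x = c(0, NA, 2, 3, NA, NA, 6),
                   y = c(0, NA, 2, 3, NA, NA, 6))
  ts <- as_track_set(df)
  out <- clean_tracks(ts, max_gap = 1)
  expect_equal(out$x[out$frame == 1], 1)   # single gap interpolated
  expect_true(all(is.na(out$x[out$frame %in% 4:5])))  # run of 2 left alone
  out2 <- clean_tracks(ts, max_gap = 2)
  expect_equal(out2$x[out2$frame %in% 4:5], c(4, 5))
})

test_that("long missing runs and edges stay missing", {
  df <- data.frame(frame = 0:9, animal = "a", bodypart = "head",
                   x = c(NA, 1, NA, NA, NA, NA, NA, 7, 8, NA),
                   y = 0)
  ts <- as_track_set(df)
  out <- clean_tracks(ts, max_gap = 3)
  expect_true(is.na(out$x[out$frame == 0]))   # leading stays missing
  expect_true(is.na(out$x[out$frame == 9]))   # trailing stays missing
  expect_true(all(is.na(out$x[out$frame %in% 2:6])))  # run of 5 > max_gap
})

test_that("moving-median smoothing matches a brute-force median oracle", {
  set.seed(11)
  t_n <- 40
  noise <- sample(c(-0.5, 0, 0.5), t_n, replace = TRUE)
  df <- data.frame(frame = 0:(t_n - 1), animal = "a", bodypart = "head",
                   x = 5 + noise, y = 3)
  ts <- as_track_set(df)
  out <- clean_tracks(ts, smooth_window = 5)
  # independent oracle: direct windowed median
  oracle <- vapply(seq_len(t_n), function(i) {
    w <- df$x[max(1, i - 2):min(t_n, i + 2)]
    median(w)
  }, numeric(1))
  expect_equal(out$x, oracle)
  # constant + symmetric noise: interior frames recover the constant
  sym <- rep(c(-0.5, 0, 0.5), length.out = t_n)
  df$x <- 5 + sym
  out2 <- clean_tracks(as_track_set(df), smooth_window = 5)
  expect_true(all(out2$x[3:(t_n - 2)] == 5))
})

test_that("cleaning is idempotent when off and never alters structure", {
  sim <- simulate_scenario(scenario_spec("RANDOM_WALK", n_frames = 30,
                                         seed = 5))
  ts <- sim$tracks
  out <- clean_tracks(ts, min_confidence = 0, max_gap = 0,
                      smooth_window = 1)
  attr(out, "cleaning_report") <- NULL
  expect_equal(tibble::as_tibble(out), tibble::as_tibble(ts))
  out2 <- clean_tracks(ts, min_confidence = 0.9, max_gap = 2,
                       smooth_window = 3)
  expect_equal(n_frames(out2), n_frames(ts))
  expect_equal(animals(out2), animals(ts))
  expect_equal(bodyparts(out2), bodyparts(ts))
})

test_that("low-confidence points are dropped and reported", {
  df <- data.frame(frame = 0:4, animal = "a", bodypart = "head",
                   x = 1:5, y = 1:5,
                   confidence = c(1, 0.1, 1, 0.2, 1))
  out <- clean_tracks(as_track_set(df), min_confidence = 0.5)
  expect_true(all(is.na(out$x[out$frame %in% c(1, 3)])))
  rep <- attr(out, "cleaning_report")
  expect_equal(rep$dropped, 2)
  # all-missing bodypart warns
  df$confidence <- 0
  expect_warning(clean_tracks(as_track_set(df), min_confidence = 0.5),
                 "all frames missing")
})
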