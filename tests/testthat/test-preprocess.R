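test_that("sampling rate is the valid fraction and empty streams error", {
  s <- tibble::tibble(valid = rep(FALSE, 10))
  expect_equal(gaze_sampling_rate(s), 0)
  s2 <- tibble::tibble(valid = rep(c(TRUE, FALSE), each = 180))
  expect_equal(gaze_sampling_rate(s2), 0.5)
  expect_error(gaze_sampling_rate(s2[0, ]),
               class = "gazeimpress_data_error")
})

test_that("the 60% rule excludes strictly-below-threshold sessions only", {
  rec <- tibble::tibble(subject_id = c("a", "b", "c"),
                        sampling_rate = c(0.59, 0.60, 0.61))
  out <- filter_sessions(rec)
  expect_equal(out$subject_id, c("b", "c"))  # exactly 0.60 is retained
  excl <- attr(out, "exclusions")
  expect_equal(excl$subject_id, "a")
  expect_match(excl$reason, "0.590")
  empty <- filter_sessions(rec[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("weight map conserves mass and peaks at the sample", {
  expect_warning(
    empty <- gaze_weight_map(tibble::tibble(x_px = numeric(0),
                                            y_px = numeric(0)),
                             canvas = c(50, 60)),
    "zero")
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(60L, 50L))

  one <- gaze_weight_map(tibble::tibble(x_px = 25, y_px = 30),
                         canvas = c(50, 60), sd = 4)
  expect_equal(sum(one), 1, tolerance = 1e-6)
  peak <- which(one == max(one), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(30, 25))
  # radial symmetry up to grid discretization
  expect_equal(one[30, 20], one[30, 30])
  expect_equal(one[25, 25], one[35, 25])

  # total mass equals the number of samples (truncation-corrected)
  n <- 37
  set.seed(1)
  samp <- tibble::tibble(x_px = runif(n, 10, 40), y_px = runif(n, 10, 50))
  map <- gaze_weight_map(samp, canvas = c(50, 60), sd = 10)
  expect_equal(sum(map), n, tolerance = 1e-6)
})

test_that("area masses match hand computation on a toy map", {
  mask <- tiny_mask()
  map <- matrix(0, 100, 80)
  expect_equal(unname(area_mass(map, mask)), c(0, 0, 0))

  # hand-placed values on a 4x4 toy with a 2-pixel eye mask
  toy_labels <- matrix(0L, 4, 4)
  toy_labels[1, 1] <- 1L; toy_labels[2, 2] <- 1L
  toy_labels[3, 3] <- 2L; toy_labels[4, 4] <- 3L
  toy_mask <- structure(list(stimulus_id = "toy", canvas = c(4L, 4L),
                             labels = toy_labels,
                             pixel_counts = c(eye = 2L, nose = 1L,
                                              mouth = 1L)),
                        class = "mask_set")
  toy_map <- matrix(as.numeric(1:16), 4, 4)
  m <- area_mass(toy_map, toy_mask)
  expect_equal(unname(m["eye"]), 1 + 6)       # cells (1,1) and (2,2)
  expect_equal(unname(m["nose"]), 11)
  expect_equal(unname(m["mouth"]), 16)

  # a mask covering the whole canvas as one area captures all mass
  all_eye <- toy_mask
  all_eye$labels <- matrix(1L, 4, 4)
  all_eye$pixel_counts <- c(eye = 16L, nose = 1L, mouth = 1L)
  expect_equal(unname(area_mass(toy_map, all_eye)["eye"]), sum(toy_map))

  expect_error(area_mass(matrix(0, 3, 3), toy_mask),
               class = "gazeimpress_data_error")
})

test_that("area weights implement the per-pixel-density normalization", {
  counts <- c(eye = 10, nose = 20, mouth = 5)
  # all mass in the eye area: clipped to 1 - 1e-6
  expect_equal(unname(area_weights(c(eye = 3, nose = 0, mouth = 0), counts)),
               c(1 - 1e-6, 0, 0))
  expect_equal(unname(area_weights(c(eye = 0, nose = 0, mouth = 0), counts)),
               c(0, 0, 0))
  # equal per-pixel density in eye and nose, none in mouth
  g <- area_weights(c(eye = 1, nose = 2, mouth = 0), counts)
  expect_equal(unname(g), c(0.5, 0.5, 0))
  expect_error(area_weights(c(eye = 1, nose = 1, mouth = 1),
                            c(eye = 0, nose = 1, mouth = 1)),
               class = "gazeimpress_config_error")
})

test_that("weights are scale invariant and masses monotone in samples", {
  mask <- tiny_mask()
  set.seed(4)
  samp <- tibble::tibble(x_px = runif(50, 5, 75), y_px = runif(50, 5, 95))
  map <- gaze_weight_map(samp, canvas = c(80, 100), sd = 5)
  g1 <- area_weights(area_mass(map, mask), mask$pixel_counts)
  g2 <- area_weights(area_mass(3.7 * map, mask), mask$pixel_counts)
  expect_equal(g1, g2)

  # adding a sample inside the nose area cannot decrease the nose mass
  m_before <- area_mass(map, mask)
  samp2 <- dplyr::bind_rows(samp, tibble::tibble(x_px = 40, y_px = 55))
  m_after <- area_mass(gaze_weight_map(samp2, canvas = c(80, 100), sd = 5),
                       mask)
  expect_gte(m_after["nose"], m_before["nose"])
})

test_that("full pipeline recovers the configured attention ordering", {
  mask <- tiny_mask()
  streams <- dplyr::bind_rows(lapply(1:3, function(i) {
    shares <- list(c(6, 3, 1), c(1, 6, 3), c(1, 3, 6))[[i]]
    sim_gaze_stream(shares, mask, seed = i, jitter_sd = 1,
                    display = c(120, 140),
                    subject_id = sprintf("S%02d", i), stimulus_id = "tiny")
  }))
  rec <- preprocess_gaze(streams, mask, canvas = c(80, 100),
                         display = c(120, 140), sd = 2,
                         exclude_by = "trial")
  g <- as.matrix(rec[, c("g_eye", "g_nose", "g_mouth")])
  expect_equal(unname(apply(g, 1, which.max)), 1:3)
})

test_that("session-level exclusion drops a subject's whole task block", {
  mask <- tiny_mask()
  good <- sim_gaze_stream(c(1, 1, 1), mask, validity = 0.95, seed = 1,
                          display = c(120, 140), subject_id = "S01")
  bad <- sim_gaze_stream(c(1, 1, 1), mask, validity = 0.40, seed = 2,
                         display = c(120, 140), subject_id = "S02")
  streams <- dplyr::bind_rows(good, bad)
  streams$task <- "Agreeableness"
  rec <- preprocess_gaze(streams, mask, canvas = c(80, 100),
                         display = c(120, 140), sd = 2)
  expect_equal(unique(rec$subject_id), "S01")
  expect_equal(unique(attr(rec, "exclusions")$subject_id), "S02")
})
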