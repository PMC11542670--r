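test_that("gaze weights follow the zero-inflated beta generative model", {
  params <- default_true_params()
  traits <- sim_traits(100, seed = 2)

  # an extreme negative Bernoulli intercept forces all-zero weights
  p0 <- params
  p0$zib$alpha_bern[] <- -20
  p0$zib$beta_bern[] <- 0
  w0 <- sim_gaze_weights(traits, p0, n_faces = 5, seed = 3)
  expect_true(all(w0$g_eye == 0 & w0$g_nose == 0 & w0$g_mouth == 0))

  # fixed q = 0.7: zero fraction ~ 0.3 within Monte-Carlo error
  pq <- params
  pq$zib$alpha_bern[] <- qlogis(0.7)
  pq$zib$beta_bern[] <- 0
  pq$zib$sigma$bern_subject[] <- 1e-6
  pq$zib$sigma$bern_face[] <- 1e-6
  wq <- sim_gaze_weights(sim_traits(200, seed = 4), pq, n_faces = 17,
                         seed = 5)
  zfrac <- mean(c(wq$g_eye, wq$g_nose, wq$g_mouth) == 0)
  n <- 3 * nrow(wq)
  expect_lt(abs(zfrac - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  # fixed mu = 0.2, phi = 10: mean of the non-zero weights ~ 0.2
  pm <- pq
  pm$zib$alpha_beta[] <- qlogis(0.2)
  pm$zib$beta_beta[] <- 0
  pm$zib$phi[] <- 10
  pm$zib$sigma$beta_subject[] <- 1e-6
  pm$zib$sigma$beta_face[] <- 1e-6
  wm <- sim_gaze_weights(sim_traits(200, seed = 6), pm, n_faces = 17,
                         seed = 7)
  g <- c(wm$g_eye, wm$g_nose, wm$g_mouth)
  g <- g[g > 0]
  beta_sd <- sqrt(0.2 * 0.8 / 11)
  expect_lt(abs(mean(g) - 0.2), 3 * beta_sd / sqrt(length(g)))
  expect_true(all(g > 0 & g < 1))
})

test_that("ratings come from the ordered-logistic pmf", {
  params <- default_true_params()
  traits <- sim_traits(20, seed = 1)
  w <- sim_gaze_weights(traits, params, n_faces = 10, seed = 2)
  r <- sim_ratings(w, traits, params, seed = 3)
  expect_true(all(r$rating %in% 1:7))

  # an overwhelming positive trait effect pins the rating at 7
  phi <- params
  phi$rating$beta_trait[] <- 20
  rhi <- sim_ratings(w, traits, phi, seed = 4)
  expect_true(all(rhi$rating == 7))

  # frequencies at a fixed linear predictor match the pmf (chi-square
  # goodness of fit at alpha = 0.01)
  pfix <- params
  pfix$rating$beta_gaze[] <- 0
  pfix$rating$beta_trait[] <- 0
  pfix$rating$cutpoints <- c(-2, -1.2, -0.4, 0.4, 1.2, 2)
  pfix$rating$sigma$subject <- 1e-6
  pfix$rating$sigma$face <- 1e-6
  big_traits <- sim_traits(100, seed = 5)
  wbig <- sim_gaze_weights(big_traits, params, n_faces = 100, seed = 6)
  rbig <- sim_ratings(wbig, big_traits, pfix, seed = 7)
  probs <- ordered_logistic_pmf(0, pfix$rating$cutpoints)
  tab <- tabulate(rbig$rating, 7)
  expect_gt(stats::chisq.test(tab, p = probs)$p.value, 0.01)
})

test_that("missing trait coverage is a data error", {
  params <- default_true_params()
  traits <- sim_traits(5, seed = 1)
  w <- sim_gaze_weights(traits, params, n_faces = 2, seed = 2)
  expect_error(sim_ratings(w, traits[1:3, ], params, seed = 3),
               class = "gazeimpress_data_error")
})

test_that("rendered gaze streams have the configured shape and validity", {
  mask <- tiny_mask()
  s <- sim_gaze_stream(c(1, 1, 1), mask, duration = 3, rate = 120,
                       validity = 1, seed = 1)
  expect_equal(nrow(s), 360L)
  expect_equal(gaze_sampling_rate(s), 1.0)
  expect_true(all(diff(s$t_ms) > 0))
  s2 <- sim_gaze_stream(c(1, 0, 0), mask, validity = 0.5, seed = 2)
  expect_lt(gaze_sampling_rate(s2), 1)
  expect_true(all(is.na(s2$x_px[!s2$valid])))
  expect_error(sim_gaze_stream(c(0, 0, 0), mask),
               class = "gazeimpress_config_error")
})

test_that("whole-study simulation is deterministic and well-formed", {
  s1 <- sim_study(n_subjects = 6, n_faces_per_task = 4,
                  tasks = impression_tasks()[1:2], seed = 9)
  s2 <- sim_study(n_subjects = 6, n_faces_per_task = 4,
                  tasks = impression_tasks()[1:2], seed = 9)
  expect_identical(s1$data, s2$data)
  # each face belongs to exactly one impression task
  expect_equal(anyDuplicated(s1$task_assignment$stimulus_id), 0L)
  # each subject x face pair appears at most once per task
  expect_equal(anyDuplicated(s1$data[, c("subject_id", "stimulus_id")]), 0L)
  expect_true(all(s1$data$rating %in% 1:7))
  expect_equal(nrow(s1$data), 6 * 4 * 2)
})

test_that("attention shares round-trip through rendering and preprocessing", {
  mask <- tiny_mask()
  s <- sim_gaze_stream(c(1, 0, 0), mask, seed = 3, jitter_sd = 0.5,
                       display = c(200, 200))
  # narrow kernel so no mass bleeds across the small test mask's areas
  rec <- preprocess_gaze(s, mask, canvas = mask$canvas,
                         display = c(200, 200), sd = 1,
                         exclude_by = "trial")
  expect_equal(rec$g_nose, 0)
  expect_equal(rec$g_mouth, 0)
  expect_gt(rec$g_eye, 1 - 2e-6)  # all density in the eye area, clipped
})
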