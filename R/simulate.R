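#' Simulate per-area gaze weights from the zero-inflated beta model
#'
#' For every subject x face pair and each area (eye, nose, mouth), draws a
#' gaze weight from the generative model: with probability `1 - q` the area
#' is never looked at (weight 0), otherwise the weight comes from
#' `Beta(phi * mu, phi * (1 - mu))`, where `q` and `mu` are logistic
#' regressions on the subject's traits plus freshly drawn subject and face
#' random intercepts (Normal(0, sigma)).
#'
#' @param traits A trait tibble from [sim_traits()].
#' @param params An [impress_params] object (ground truth).
#' @param n_faces Number of face stimuli.
#' @param task Impression-task label attached to the records.
#' @param seed Optional integer seed.
#' @param stimulus_ids Optional stimulus identifiers (length `n_faces`).
#' @return A tibble with columns `subject_id`, `stimulus_id`, `task`,
#'   `g_eye`, `g_nose`, `g_mouth` (each in `[0, 1)`), carrying the drawn
#'   random effects in attribute `"ranef"`.
#' @export
sim_gaze_weights <- function(traits, params, n_faces, task = "Extraversion",
                             seed = NULL, stimulus_ids = NULL) {
  validate_params(params)
  if (!is_count(n_faces, 1L)) stop_config("`n_faces` must be a count >= 1")
  z <- params$zib
  ns <- nrow(traits)
  stimulus_ids <- stimulus_ids %||% sprintf("F%03d", seq_len(n_faces))
  with_seed(seed, {
    ranef <- list(
      bern_subject = matrix(rnorm(ns * 3, 0, rep(z$sigma$bern_subject, each = ns)), ns, 3),
      bern_face    = matrix(rnorm(n_faces * 3, 0, rep(z$sigma$bern_face, each = n_faces)), n_faces, 3),
      beta_subject = matrix(rnorm(ns * 3, 0, rep(z$sigma$beta_subject, each = ns)), ns, 3),
      beta_face    = matrix(rnorm(n_faces * 3, 0, rep(z$sigma$beta_face, each = n_faces)), n_faces, 3)
    )
    si <- rep(seq_len(ns), each = n_faces)
    fi <- rep(seq_len(n_faces), ns)
    p <- as.matrix(traits[.traits])
    G <- matrix(0, length(si), 3)
    for (k in 1:3) {
      q <- bern_prob(p[si, , drop = FALSE], z$alpha_bern[k], z$beta_bern[k, ],
                     ranef$bern_subject[si, k], ranef$bern_face[fi, k])
      mu <- beta_mean(p[si, , drop = FALSE], z$alpha_beta[k], z$beta_beta[k, ],
                      ranef$beta_subject[si, k], ranef$beta_face[fi, k])
      looked <- rbinom(length(q), 1L, q) == 1L
      g <- numeric(length(q))
      if (any(looked)) {
        draw <- rbeta(sum(looked), z$phi[k] * mu[looked],
                      z$phi[k] * (1 - mu[looked]))
        # keep positive draws strictly inside (0, 1) for the beta likelihood
        g[looked] <- pmin(pmax(draw, 1e-9), 1 - 1e-6)
      }
      G[, k] <- g
    }
    out <- tibble(
      subject_id = traits$subject_id[si],
      stimulus_id = stimulus_ids[fi],
      task = task,
      g_eye = G[, 1], g_nose = G[, 2], g_mouth = G[, 3]
    )
    attr(out, "ranef") <- ranef
    out
  })
}

#' Simulate impression ratings from the ordered-logistic model
#'
#' Draws a 7-point rating for every row of a gaze-weight table from the
#' ordered-logistic pmf at the rating linear predictor (gaze main effects
#' and interactions, trait effects, fresh subject and face random
#' intercepts).
#'
#' @param gaze_weights Tibble from [sim_gaze_weights()] (or preprocessed
#'   records with the same columns).
#' @inheritParams sim_gaze_weights
#' @return The input tibble with a `rating` column in `1..7` appended;
#'   rating random effects in attribute `"ranef"`.
#' @export
sim_ratings <- function(gaze_weights, traits, params, seed = NULL) {
  validate_params(params)
  r <- params$rating
  missing <- setdiff(unique(gaze_weights$subject_id), traits$subject_id)
  if (length(missing) > 0) {
    stop_data(sprintf("no trait scores for subject(s): %s",
                      paste(missing, collapse = ", ")))
  }
  subjects <- unique(gaze_weights$subject_id)
  faces <- unique(gaze_weights$stimulus_id)
  si <- match(gaze_weights$subject_id, subjects)
  fi <- match(gaze_weights$stimulus_id, faces)
  p <- as.matrix(traits[match(subjects, traits$subject_id), .traits])
  with_seed(seed, {
    ranef <- list(rating_subject = rnorm(length(subjects), 0, r$sigma$subject),
                  rating_face = rnorm(length(faces), 0, r$sigma$face))
    eta <- rating_linpred(as.matrix(gaze_weights[paste0("g_", .areas)]),
                          r$beta_gaze, p[si, , drop = FALSE], r$beta_trait,
                          ranef$rating_subject[si], ranef$rating_face[fi])
    pm <- ordered_logistic_pmf(eta, r$cutpoints)
    pm <- rbind(pm)
    rating <- vapply(seq_len(nrow(pm)), function(i) {
      sample.int(7L, 1L, prob = pm[i, ])
    }, integer(1))
    out <- mutate(gaze_weights, rating = rating)
    attr(out, "ranef") <- ranef
    out
  })
}

#' Render a raw gaze stream over a masked stimulus
#'
#' Emulates a monitor-mounted eye tracker recording (default 120 Hz for
#' 3 s): each sample picks an area according to `shares`, lands uniformly
#' on a pixel of that area plus Gaussian jitter (sd 5 px), and is reported
#' in display coordinates with the stimulus centered on the display.
#' A fraction `1 - validity` of samples is flagged invalid (coordinates
#' missing), emulating blinks and track loss.
#'
#' @param shares Non-negative attention shares for eye, nose, mouth (need
#'   not sum to 1; at least one must be positive).
#' @param mask_set A [sim_masks()] mask set.
#' @param duration Recording duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param validity Fraction of valid samples in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param subject_id,stimulus_id Identifiers stamped on the stream.
#' @param jitter_sd Gaussian jitter around the sampled pixel, in px.
#' @param display Display resolution (width, height) in px.
#' @return A tibble with columns `subject_id`, `stimulus_id`, `t_ms`,
#'   `x_px`, `y_px`, `valid`; `floor(duration * rate)` rows.
#' @export
sim_gaze_stream <- function(shares, mask_set, duration = 3, rate = 120,
                            validity = 1, seed = NULL,
                            subject_id = "S001", stimulus_id = "F001",
                            jitter_sd = 5, display = c(1024, 768)) {
  stopifnot(inherits(mask_set, "mask_set"))
  if (length(shares) != 3L || any(shares < 0)) {
    stop_config("`shares` must be 3 non-negative numbers (eye, nose, mouth)")
  }
  if (sum(shares) == 0) stop_config("at least one attention share must be > 0")
  assert_scalar_number(duration, "duration", lower = 1e-9)
  assert_scalar_number(rate, "rate", lower = 1e-9)
  assert_scalar_number(validity, "validity", lower = 0, upper = 1)
  n <- floor(duration * rate)
  off <- (display - mask_set$canvas) / 2
  with_seed(seed, {
    area <- sample.int(3L, n, replace = TRUE, prob = shares / sum(shares))
    pixels <- lapply(1:3, function(k) which(mask_set$labels == k))
    idx <- vapply(area, function(k) {
      pixels[[k]][sample.int(length(pixels[[k]]), 1L)]
    }, integer(1))
    # labels is height x width: row = y, col = x
    h <- nrow(mask_set$labels)
    x <- ((idx - 1L) %/% h) + 1L + rnorm(n, 0, jitter_sd) + off[1]
    y <- ((idx - 1L) %% h) + 1L + rnorm(n, 0, jitter_sd) + off[2]
    valid <- runif(n) < validity
    tibble(subject_id = subject_id, stimulus_id = stimulus_id,
           t_ms = (seq_len(n) - 1) * 1000 / rate,
           x_px = ifelse(valid, x, NA_real_),
           y_px = ifelse(valid, y, NA_real_),
           valid = valid)
  })
}

#' Simulate a complete synthetic study
#'
#' Generates, from known ground-truth parameters, everything a study of one
#' or more impression tasks produces: subject trait profiles, per-task face
#' sets (each face appears in exactly one task), gaze weights from the
#' zero-inflated beta model, and 7-point ratings from the ordered-logistic
#' model. The joined analysis table (`$data`) has one row per
#' subject x face with gaze weights, rating and trait scores, ready for
#' [fit_joint()].
#'
#' @param n_subjects Number of subjects.
#' @param n_faces_per_task Faces per impression task.
#' @param tasks Impression-task labels (default: the first task only; use
#'   [impression_tasks()] for the full five-task design).
#' @param params Ground-truth [impress_params].
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return An `impress_study` list: `traits`, `weights`, `data` (per-task
#'   joined tables, bound), `params`, `task_assignment`, `seed`.
#' @export
#' @examples
#' study <- sim_study(n_subjects = 8, n_faces_per_task = 4, seed = 1)
#' head(study$data)
sim_study <- function(n_subjects = 34, n_faces_per_task = 10,
                      tasks = impression_tasks()[1], params = default_true_params(),
                      seed = NULL) {
  validate_params(params)
  traits <- sim_traits(n_subjects, seed = child_seed(seed, "traits"))
  all_faces <- sprintf("F%03d", seq_len(n_faces_per_task * length(tasks)))
  assignment <- tibble(
    stimulus_id = all_faces,
    task = rep(tasks, each = n_faces_per_task)
  )
  per_task <- lapply(seq_along(tasks), function(t) {
    ids <- assignment$stimulus_id[assignment$task == tasks[t]]
    w <- sim_gaze_weights(traits, params, n_faces_per_task, task = tasks[t],
                          seed = child_seed(seed, paste0("gaze", t)),
                          stimulus_ids = ids)
    sim_ratings(w, traits, params,
                seed = child_seed(seed, paste0("rating", t)))
  })
  data <- bind_rows(per_task) %>%
    left_join(traits, by = "subject_id")
  structure(list(traits = traits, weights = bind_rows(per_task),
                 data = data, params = params,
                 task_assignment = assignment, seed = seed),
            class = "impress_study")
}

#' Simulate a between-condition rating study
#'
#' Generates ratings under the gaze-manipulation design: subjects are split
#' across the Free, Eye, Nose and Mouth conditions (between-subject), and
#' each subject rates the same face set; ratings come from the
#' ordered-logistic condition model (reference-coded condition effects with
#' `Free` fixed at 0, subject and face random intercepts).
#'
#' @param n_per_condition Named counts of subjects per condition; any subset
#'   of `gaze_conditions()` with at least two conditions.
#' @param n_faces Number of faces rated by every subject.
#' @param params Ground-truth [impress_params] with a `condition` block.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `stimulus_id`, `condition`,
#'   `rating`.
#' @export
sim_condition_study <- function(n_per_condition = c(Free = 34, Eye = 34,
                                                    Nose = 34, Mouth = 35),
                                n_faces = 10, params = default_true_params(),
                                seed = NULL) {
  validate_params(params)
  if (is.null(params$condition)) stop_config("`params` has no condition block")
  if (!all(names(n_per_condition) %in% .conditions) ||
      length(n_per_condition) < 2L) {
    stop_config("`n_per_condition` must name >= 2 of the Free/Eye/Nose/Mouth conditions")
  }
  cn <- params$condition
  ns <- sum(n_per_condition)
  cond <- rep(names(n_per_condition), n_per_condition)
  subjects <- sprintf("S%03d", seq_len(ns))
  faces <- sprintf("F%03d", seq_len(n_faces))
  with_seed(child_seed(seed, "condition"), {
    rs <- rnorm(ns, 0, cn$sigma$subject)
    rf <- rnorm(n_faces, 0, cn$sigma$face)
    si <- rep(seq_len(ns), each = n_faces)
    fi <- rep(seq_len(n_faces), ns)
    eta <- condition_linpred(cond[si], cn$beta, rs[si], rf[fi])
    pm <- rbind(ordered_logistic_pmf(eta, cn$cutpoints))
    rating <- vapply(seq_len(nrow(pm)), function(i) {
      sample.int(7L, 1L, prob = pm[i, ])
    }, integer(1))
    tibble(subject_id = subjects[si], stimulus_id = faces[fi],
           condition = cond[si], rating = rating)
  })
}
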