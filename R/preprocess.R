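#' Eye-tracking sampling rate
#'
#' Fraction of samples in a gaze stream that the tracker flagged valid.
#' Streams with a rate below 60% are conventionally excluded downstream
#' (see [filter_sessions()]).
#'
#' @param stream A gaze-stream tibble with a logical `valid` column.
#' @return A fraction in `[0, 1]`.
#' @export
gaze_sampling_rate <- function(stream) {
  if (nrow(stream) == 0L) stop_data("empty gaze stream")
  mean(stream$valid)
}

#' Apply the sampling-rate exclusion rule
#'
#' Retains records whose sampling rate is at least `threshold`; rates
#' strictly below it are excluded (a rate of exactly 0.60 is retained under
#' the default). Exclusions are returned in the `"exclusions"` attribute
#' with a reason per record.
#'
#' @param records A tibble with a `sampling_rate` column.
#' @param threshold Exclusion threshold (default 0.60).
#' @return The retained rows, with an `"exclusions"` attribute holding the
#'   dropped rows plus a `reason` column.
#' @export
filter_sessions <- function(records, threshold = 0.60) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (!"sampling_rate" %in% names(records)) {
    stop_data("`records` must carry a `sampling_rate` column")
  }
  keep <- records$sampling_rate >= threshold
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- sprintf("sampling rate %.3f below threshold %.2f",
                               excluded$sampling_rate, threshold)
  } else {
    excluded$reason <- character(0)
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- excluded
  out
}

#' Map display-coordinate samples into stimulus coordinates
#'
#' The stimulus canvas is assumed centered on the display; valid samples
#' are translated accordingly and samples falling off the canvas are
#' dropped (they still count toward the sampling rate, which is computed
#' from the raw stream).
#'
#' @param stream Gaze-stream tibble (display coordinates).
#' @param canvas Stimulus size (width, height) in px.
#' @param display Display resolution (width, height) in px.
#' @return Tibble of on-canvas valid samples with `x_px`, `y_px` in
#'   stimulus coordinates.
#' @export
to_stimulus_coords <- function(stream, canvas = c(412, 558),
                               display = c(1024, 768)) {
  off <- (display - canvas) / 2
  out <- stream %>%
    filter(.data$valid) %>%
    mutate(x_px = .data$x_px - off[1], y_px = .data$y_px - off[2])
  out %>% filter(.data$x_px >= 0.5, .data$x_px <= canvas[1] + 0.5,
                 .data$y_px >= 0.5, .data$y_px <= canvas[2] + 0.5)
}

#' Gaze weight map: superimposed Gaussian kernels
#'
#' Each valid sample contributes an isotropic Gaussian kernel (sd 10 px by
#' default) evaluated at pixel centers, truncated at 4 sd and renormalized
#' to unit mass on the canvas; the map is the sum over samples, so its
#' total mass equals the number of samples used.
#'
#' @param samples Tibble of samples in stimulus coordinates (`x_px`,
#'   `y_px`), e.g. from [to_stimulus_coords()].
#' @param canvas Stimulus size (width, height) in px.
#' @param sd Kernel standard deviation in px.
#' @return A `height x width` matrix of non-negative weights (row = y,
#'   column = x).
#' @export
gaze_weight_map <- function(samples, canvas = c(412, 558), sd = 10) {
  assert_scalar_number(sd, "sd", lower = 1e-9)
  w <- canvas[1]; h <- canvas[2]
  map <- matrix(0, nrow = h, ncol = w)
  if (nrow(samples) == 0L) {
    warn("no usable samples: returning an all-zero weight map")
    return(map)
  }
  half <- ceiling(4 * sd)
  for (i in seq_len(nrow(samples))) {
    x <- samples$x_px[i]; y <- samples$y_px[i]
    xs <- max(1, round(x) - half):min(w, round(x) + half)
    ys <- max(1, round(y) - half):min(h, round(y) + half)
    patch <- dnorm(ys, y, sd) %o% dnorm(xs, x, sd)
    map[ys, xs] <- map[ys, xs] + patch / sum(patch)
  }
  map
}

#' Per-area mass of a weight map
#'
#' Sums the weight map over the pixels of each masked area; mass outside
#' all areas is discarded.
#'
#' @param map Weight map from [gaze_weight_map()].
#' @param mask_set A [sim_masks()] mask set on the same canvas.
#' @return Named numeric vector `(eye, nose, mouth)`.
#' @export
area_mass <- function(map, mask_set) {
  stopifnot(inherits(mask_set, "mask_set"))
  if (!identical(dim(map), dim(mask_set$labels))) {
    stop_data("weight map and mask canvas dimensions differ")
  }
  vapply(1:3, function(k) sum(map[mask_set$labels == k]),
         numeric(1)) %>% setNames(.areas)
}

#' Normalized per-area gaze weights
#'
#' Converts per-area masses into the `[0, 1)` gaze weights used by the
#' zero-inflated beta model: each mass is divided by the area's pixel count
#' (per-pixel density, the size correction), then densities are normalized
#' to relative shares across the three areas. A share of exactly 1 is
#' clipped to `1 - 1e-6` so weights stay inside the beta support; if no
#' area carries mass, all weights are 0.
#'
#' @param masses Named masses from [area_mass()].
#' @param pixel_counts Per-area pixel counts (> 0).
#' @return Named numeric vector `(eye, nose, mouth)`, each in `[0, 1)`.
#' @export
area_weights <- function(masses, pixel_counts) {
  if (any(pixel_counts <= 0)) stop_config("pixel counts must be > 0")
  dens <- masses / pixel_counts
  if (all(dens == 0)) return(setNames(c(0, 0, 0), .areas))
  g <- dens / sum(dens)
  g[g >= 1] <- 1 - 1e-6
  setNames(as.numeric(g), .areas)
}

#' Preprocess raw gaze streams into area-weight records
#'
#' Full preprocessing pipeline: per trial (subject x stimulus), compute the
#' sampling rate, map valid samples into stimulus coordinates, build the
#' Gaussian-kernel weight map, mask it, and normalize per-area masses into
#' gaze weights. The sampling-rate exclusion (default 60%) is applied
#' either per session (subject x task, pooling all of the session's
#' samples; the default) or per trial.
#'
#' @param streams Gaze samples for any number of trials: tibble with
#'   `subject_id`, `stimulus_id`, `t_ms`, `x_px`, `y_px`, `valid` and
#'   optionally `task` / `condition`.
#' @param masks A single [sim_masks()] mask set (used for every stimulus)
#'   or a named list of mask sets keyed by `stimulus_id`.
#' @param canvas,display,sd See [gaze_weight_map()] and
#'   [to_stimulus_coords()].
#' @param threshold Sampling-rate exclusion threshold.
#' @param exclude_by `"session"` (subject x task) or `"trial"`
#'   (subject x stimulus).
#' @return A tibble of area-weight records (`subject_id`, `stimulus_id`,
#'   optional `task`/`condition`, `g_eye`, `g_nose`, `g_mouth`,
#'   `sampling_rate`), with dropped records in the `"exclusions"`
#'   attribute.
#' @export
preprocess_gaze <- function(streams, masks, canvas = c(412, 558),
                            display = c(1024, 768), sd = 10,
                            threshold = 0.60,
                            exclude_by = c("session", "trial")) {
  exclude_by <- match.arg(exclude_by)
  keys <- intersect(c("subject_id", "stimulus_id", "task", "condition"),
                    names(streams))
  trials <- streams %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)))
  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, ]
    s <- dplyr::semi_join(streams, trial, by = keys)
    rate <- gaze_sampling_rate(s)
    on_canvas <- to_stimulus_coords(s, canvas, display)
    mask <- if (inherits(masks, "mask_set")) masks else {
      masks[[trial$stimulus_id]] %||%
        stop_data(sprintf("no mask for stimulus %s", trial$stimulus_id))
    }
    map <- if (nrow(on_canvas) == 0L) {
      matrix(0, canvas[2], canvas[1])
    } else {
      gaze_weight_map(on_canvas, canvas, sd)
    }
    g <- unname(area_weights(area_mass(map, mask), mask$pixel_counts))
    dplyr::bind_cols(trial, tibble(g_eye = g[1], g_nose = g[2],
                                   g_mouth = g[3], sampling_rate = rate))
  })
  records <- bind_rows(rows)
  if (exclude_by == "trial" || !"task" %in% keys) {
    return(filter_sessions(records, threshold))
  }
  # session mode: pool each subject x task session's samples for the rate
  session_rate <- streams %>%
    group_by(.data$subject_id, .data$task) %>%
    summarise(session_rate = mean(.data$valid), .groups = "drop")
  records <- left_join(records, session_rate, by = c("subject_id", "task"))
  keep <- records$session_rate >= threshold
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- sprintf("session sampling rate %.3f below threshold %.2f",
                               excluded$session_rate, threshold)
  } else {
    excluded$reason <- character(0)
  }
  out <- records[keep, , drop = FALSE] %>% select(-"session_rate")
  attr(out, "exclusions") <- excluded
  out
}
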