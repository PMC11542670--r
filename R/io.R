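# File formats: gaze/trait/rating/weight CSVs, mask rasters (PNG) and
# polygon masks (JSON), study configuration (YAML).

gaze_cols <- c("subject_id", "stimulus_id", "t_ms", "x_px", "y_px", "valid")

#' Read and write gaze-stream CSV files
#'
#' Schema: `subject_id, stimulus_id, t_ms, x_px, y_px, valid` (plus any
#' extra columns, e.g. `task`). Coordinates of invalid samples may be
#' empty. Timestamps must be non-decreasing within each
#' subject x stimulus stream; violations are reported with their row
#' number.
#'
#' @param path CSV path.
#' @param streams Gaze-sample tibble.
#' @return `read_gaze_csv()` returns the validated tibble;
#'   `write_gaze_csv()` returns `path` invisibly. A write-then-read round
#'   trip preserves values.
#' @export
read_gaze_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(gaze_cols, names(x))
  if (length(missing) > 0) {
    stop_data(sprintf("gaze file %s lacks column(s): %s", path,
                      paste(missing, collapse = ", ")))
  }
  x$valid <- as.logical(x$valid)
  bad <- x %>%
    mutate(row = dplyr::row_number()) %>%
    group_by(.data$subject_id, .data$stimulus_id) %>%
    filter(c(FALSE, diff(.data$t_ms) < 0)) %>%
    ungroup()
  if (nrow(bad) > 0) {
    stop_data(sprintf("timestamps out of order at row %d of %s",
                      bad$row[1], path))
  }
  x
}

#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(streams, path) {
  missing <- setdiff(gaze_cols, names(streams))
  if (length(missing) > 0) {
    stop_data(sprintf("gaze table lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  readr::write_csv(streams, path, progress = FALSE)
  invisible(path)
}

#' Read and write trait, rating and area-weight CSV files
#'
#' Thin schema-checked wrappers: traits require `subject_id` plus the five
#' trait columns (scores in `[1, 7]`); ratings require `subject_id`,
#' `stimulus_id`, `rating` in 1..7; area weights require `subject_id`,
#' `stimulus_id` and the three `g_*` columns in `[0, 1)`.
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @return Readers return the validated tibble; writers return `path`
#'   invisibly.
#' @export
read_traits_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("subject_id", .traits), names(x))
  if (length(missing) > 0) {
    stop_data(sprintf("trait file lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if (any(as.matrix(x[, .traits]) < 1 | as.matrix(x[, .traits]) > 7)) {
    stop_data("trait scores must lie in [1, 7]")
  }
  x
}

#' @rdname read_traits_csv
#' @export
write_traits_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_traits_csv
#' @export
read_ratings_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("subject_id", "stimulus_id", "rating"), names(x))
  if (length(missing) > 0) {
    stop_data(sprintf("rating file lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if (any(!x$rating %in% 1:7)) stop_data("ratings must lie in 1..7")
  x
}

#' @rdname read_traits_csv
#' @export
write_ratings_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_traits_csv
#' @export
read_weights_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  gcols <- paste0("g_", .areas)
  missing <- setdiff(c("subject_id", "stimulus_id", gcols), names(x))
  if (length(missing) > 0) {
    stop_data(sprintf("weight file lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  G <- as.matrix(x[, gcols])
  if (any(G < 0 | G >= 1)) stop_data("gaze weights must lie in [0, 1)")
  x
}

#' @rdname read_traits_csv
#' @export
write_weights_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write mask label rasters (PNG)
#'
#' Label coding: 0 background, 1 eye, 2 nose, 3 mouth (stored as grayscale
#' PNG with value `label / 255`). Unknown labels and empty areas are
#' errors.
#'
#' @param mask_set A [sim_masks()] mask set.
#' @param path PNG path.
#' @param stimulus_id Identifier for the mask read.
#' @return `read_mask_png()` returns a `mask_set`; the writer returns
#'   `path` invisibly.
#' @export
write_mask_png <- function(mask_set, path) {
  stopifnot(inherits(mask_set, "mask_set"))
  png::writePNG(mask_set$labels / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, stimulus_id = "stim") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- round(img * 255)
  if (any(!labels %in% 0:3)) {
    stop_data(sprintf("mask %s contains label values outside 0..3", path))
  }
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))
  counts <- vapply(1:3, function(k) sum(labels == k), integer(1))
  if (any(counts == 0L)) {
    stop_data(sprintf("mask %s has empty area(s): %s", path,
                      paste(.areas[counts == 0L], collapse = ", ")))
  }
  structure(list(stimulus_id = stimulus_id,
                 canvas = c(ncol(labels), nrow(labels)),
                 labels = labels, pixel_counts = setNames(counts, .areas)),
            class = "mask_set")
}

# even-odd-rule point-in-polygon for all pixel centers of a canvas;
# returns a logical height x width matrix
rasterize_polygon <- function(xs, ys, canvas) {
  w <- canvas[1]; h <- canvas[2]
  inside <- matrix(FALSE, h, w)
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), w)
  n <- length(xs)
  j <- n
  hits <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    hits <- xor(hits, crosses)
    j <- i
  }
  inside[cbind(py, px)] <- hits
  inside
}

#' Read and write polygon masks (JSON)
#'
#' Polygon masks store, per area, one or more polygons as `x`/`y` vertex
#' arrays in canvas coordinates; reading rasterizes them (even-odd rule at
#' pixel centers) into a label raster. Overlapping areas are an error.
#'
#' @param polygons Named list (`eye`, `nose`, `mouth`) of polygon lists;
#'   each polygon is `list(x = ..., y = ...)`.
#' @param canvas Canvas size (width, height).
#' @param path JSON path.
#' @param stimulus_id Identifier for the mask set.
#' @return `read_mask_json()` returns a `mask_set`; the writer returns
#'   `path` invisibly.
#' @export
write_mask_json <- function(polygons, canvas, path) {
  if (!setequal(names(polygons), .areas)) {
    stop_data("polygon masks must name areas eye, nose, mouth")
  }
  jsonlite::write_json(list(canvas = canvas, areas = polygons), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path, stimulus_id = "stim") {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  canvas <- as.integer(unlist(spec$canvas))
  labels <- matrix(0L, canvas[2], canvas[1])
  for (k in seq_along(.areas)) {
    polys <- spec$areas[[.areas[k]]]
    for (poly in polys) {
      inside <- rasterize_polygon(unlist(poly$x), unlist(poly$y), canvas)
      clash <- labels[inside]
      if (any(clash != 0L & clash != k)) {
        stop_data(sprintf("mask areas overlap in %s: %s and %s", path,
                          .areas[k],
                          paste(.areas[unique(clash[clash != 0 & clash != k])],
                                collapse = ", ")))
      }
      labels[inside] <- k
    }
  }
  counts <- vapply(1:3, function(k) sum(labels == k), integer(1))
  if (any(counts == 0L)) {
    stop_data(sprintf("mask %s has empty area(s): %s", path,
                      paste(.areas[counts == 0L], collapse = ", ")))
  }
  structure(list(stimulus_id = stimulus_id, canvas = canvas,
                 labels = labels, pixel_counts = setNames(counts, .areas)),
            class = "mask_set")
}

#' Convert an ellipse mask layout to polygons
#'
#' @param layout A [default_mask_layout()]-style list.
#' @param n_vertices Vertices per ellipse outline.
#' @return Named list of polygon lists suitable for [write_mask_json()].
#' @export
layout_to_polygons <- function(layout, n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  lapply(layout, function(area) {
    lapply(area, function(e) {
      list(x = e$cx + e$rx * cos(th), y = e$cy + e$ry * sin(th))
    })
  })
}

#' Study configuration files
#'
#' A single YAML file holding the pipeline settings: canvas and display
#' sizes, kernel sd, sampling-rate threshold, MCMC settings and the
#' top-level seed. Values outside their valid ranges are rejected;
#' configuration round-trips through write/read unchanged.
#'
#' @param canvas,display Pixel sizes (width, height).
#' @param kernel_sd Gaussian kernel sd in px.
#' @param threshold Sampling-rate exclusion threshold in `[0, 1]`.
#' @param exclude_by `"session"` or `"trial"`.
#' @param mcmc An [mcmc_config()].
#' @param n_subjects,n_faces_per_task Study sizes (for `simulate`).
#' @param seed Top-level integer seed; every stage derives its streams
#'   from it.
#' @param path YAML path.
#' @param config A `study_config` object.
#' @return `study_config()` and `read_study_config()` return a
#'   `study_config` list; `write_study_config()` returns `path`
#'   invisibly.
#' @export
study_config <- function(canvas = c(412, 558), display = c(1024, 768),
                         kernel_sd = 10, threshold = 0.60,
                         exclude_by = "session", mcmc = mcmc_config(),
                         n_subjects = 34, n_faces_per_task = 10, seed = 1) {
  assert_scalar_number(kernel_sd, "kernel_sd", lower = 1e-9)
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (!exclude_by %in% c("session", "trial")) {
    stop_config("`exclude_by` must be 'session' or 'trial'")
  }
  if (!is_count(n_subjects, 1L) || !is_count(n_faces_per_task, 1L)) {
    stop_config("study sizes must be counts >= 1")
  }
  stopifnot(inherits(mcmc, "mcmc_config"))
  structure(list(canvas = canvas, display = display, kernel_sd = kernel_sd,
                 threshold = threshold, exclude_by = exclude_by,
                 mcmc = unclass(mcmc), n_subjects = n_subjects,
                 n_faces_per_task = n_faces_per_task, seed = seed),
            class = "study_config")
}

#' @rdname study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  study_config(canvas = unlist(raw$canvas), display = unlist(raw$display),
               kernel_sd = raw$kernel_sd, threshold = raw$threshold,
               exclude_by = raw$exclude_by,
               mcmc = do.call(mcmc_config, raw$mcmc),
               n_subjects = raw$n_subjects,
               n_faces_per_task = raw$n_faces_per_task, seed = raw$seed)
}

#' Persist posterior draws as CSV
#'
#' Long-format columnar export (`chain`, `iteration`, `term`, `value`)
#' with a sidecar of fit metadata, so that summary stages can run from
#' files.
#'
#' @param fit An `impress_fit`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "impress_fit"))
  wide <- as_tibble(fit$draws)
  wide$chain <- fit$chain
  wide$iteration <- stats::ave(fit$chain, fit$chain, FUN = seq_along)
  wide$lp <- fit$lp
  long <- tidyr::pivot_longer(wide, cols = -c("chain", "iteration", "lp"),
                              names_to = "term", values_to = "value")
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}
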