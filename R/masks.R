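#' Area-of-interest masks
#'
#' `sim_masks()` builds a synthetic stand-in for hand-drawn facial area
#' masks: elliptical eye, nose and mouth regions rasterized onto the
#' stimulus canvas (default 412 x 558 px). The result is a label raster
#' (0 background, 1 eye, 2 nose, 3 mouth) plus per-area pixel counts.
#'
#' @param canvas Width and height in pixels.
#' @param layout A list of ellipse sets, one per area, as produced by
#'   [default_mask_layout()]: each area is a list of ellipses
#'   `list(cx, cy, rx, ry)` in canvas coordinates.
#' @param stimulus_id Identifier attached to the mask set.
#' @return A `mask_set` object: list with `stimulus_id`, `canvas`, `labels`
#'   (height x width integer matrix) and `pixel_counts` (named, per area).
#' @export
#' @examples
#' m <- sim_masks()
#' m$pixel_counts
sim_masks <- function(canvas = c(412, 558), layout = default_mask_layout(canvas),
                      stimulus_id = "stim") {
  stopifnot(length(canvas) == 2L, all(canvas >= 1))
  if (!setequal(names(layout), .areas)) {
    stop_config("`layout` must have components eye, nose, mouth")
  }
  labels <- matrix(0L, nrow = canvas[2], ncol = canvas[1])
  for (k in seq_along(.areas)) {
    for (e in layout[[.areas[k]]]) {
      px <- rasterize_ellipse(e, canvas)
      hit <- labels[px]
      if (any(hit != 0L & hit != k)) {
        other <- .areas[unique(hit[hit != 0L & hit != k])]
        stop_config(sprintf("mask areas overlap: %s and %s",
                            .areas[k], paste(other, collapse = ", ")))
      }
      labels[px] <- k
    }
  }
  counts <- vapply(1:3, function(k) sum(labels == k), integer(1))
  if (any(counts == 0L)) {
    stop_config(sprintf("empty mask area(s): %s",
                        paste(.areas[counts == 0L], collapse = ", ")))
  }
  structure(list(stimulus_id = stimulus_id, canvas = as.integer(canvas),
                 labels = labels, pixel_counts = setNames(counts, .areas)),
            class = "mask_set")
}

# linear indices (into a height x width matrix) of pixels whose centers lie
# inside the ellipse; pixel (x, y) has center (x, y), 1-based
rasterize_ellipse <- function(e, canvas) {
  if (e$cx - e$rx < 1 || e$cx + e$rx > canvas[1] ||
      e$cy - e$ry < 1 || e$cy + e$ry > canvas[2]) {
    stop_config("ellipse does not fit within the canvas")
  }
  xs <- seq(max(1, floor(e$cx - e$rx)), min(canvas[1], ceiling(e$cx + e$rx)))
  ys <- seq(max(1, floor(e$cy - e$ry)), min(canvas[2], ceiling(e$cy + e$ry)))
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  inside <- ((gx - e$cx) / e$rx)^2 + ((gy - e$cy) / e$ry)^2 <= 1
  cbind(gy[inside], gx[inside])
}

#' @rdname sim_masks
#' @export
default_mask_layout <- function(canvas = c(412, 558)) {
  w <- canvas[1]; h <- canvas[2]
  list(
    eye = list(list(cx = 0.32 * w, cy = 0.40 * h, rx = 0.11 * w, ry = 0.045 * h),
               list(cx = 0.68 * w, cy = 0.40 * h, rx = 0.11 * w, ry = 0.045 * h)),
    nose = list(list(cx = 0.50 * w, cy = 0.56 * h, rx = 0.085 * w, ry = 0.085 * h)),
    mouth = list(list(cx = 0.50 * w, cy = 0.74 * h, rx = 0.14 * w, ry = 0.05 * h))
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set %s> canvas %d x %d px; pixels: eye %d, nose %d, mouth %d\n",
              x$stimulus_id, x$canvas[1], x$canvas[2],
              x$pixel_counts["eye"], x$pixel_counts["nose"],
              x$pixel_counts["mouth"]))
  invisible(x)
}
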