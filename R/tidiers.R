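#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fit
#'
#' One row per parameter with posterior mean, standard deviation, 95% HDI
#' bounds, split R-hat and the HDI-excludes-0 significance flag.
#'
#' @param x An `impress_fit`.
#' @param effects Which parameter classes to include: `"fixed"` (default:
#'   fixed effects, cutpoints, precisions), `"ranef"`, `"scale"`, or
#'   `"all"`.
#' @param mass HDI mass.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block`, `class`, `area`,
#'   `predictor`, `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `rhat`, `significant`.
#' @export
tidy.impress_fit <- function(x, effects = c("fixed", "ranef", "scale", "all"),
                             mass = 0.95, ...) {
  effects <- match.arg(effects)
  meta <- x$meta
  keep <- switch(effects,
    fixed = meta$class %in% c("fixed", "cutpoint", "precision"),
    ranef = meta$class == "ranef",
    scale = meta$class == "scale",
    all = rep(TRUE, nrow(meta))
  )
  meta <- meta[keep, ]
  hdis <- t(vapply(meta$term, function(tm) hdi(x$draws[, tm], mass),
                   numeric(2)))
  tibble(
    term = meta$term, block = meta$block, class = meta$class,
    area = meta$area, predictor = meta$predictor,
    estimate = colMeans(x$draws[, meta$term, drop = FALSE]),
    std.error = apply(x$draws[, meta$term, drop = FALSE], 2, sd),
    conf.low = hdis[, 1], conf.high = hdis[, 2],
    rhat = unname(x$rhat[meta$term]),
    significant = hdis[, 1] > 0 | hdis[, 2] < 0
  )
}

#' Fit-level summary
#'
#' @param x An `impress_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model type, data sizes, sampler settings,
#'   maximum split R-hat, convergence flag, mean acceptance rate and
#'   divergence count.
#' @export
glance.impress_fit <- function(x, ...) {
  tibble(
    model = x$model,
    n_obs = nrow(x$data),
    n_subjects = length(x$subjects),
    n_faces = length(x$faces),
    chains = length(unique(x$chain)),
    draws = nrow(x$draws),
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = convergence_ok(x),
    accept_rate = mean(x$accept_rate),
    divergences = x$divergences
  )
}
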