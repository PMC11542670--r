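#' Posterior point estimates
#'
#' `map_estimate()` returns the retained draw with the highest joint
#' log-posterior (the maximum a posteriori draw); `posterior_mean()` the
#' mean of each parameter's draws. Both are named vectors over the fit's
#' parameters on the raw covariate scale.
#'
#' @param fit An `impress_fit`.
#' @return Named numeric vector.
#' @export
map_estimate <- function(fit) {
  stopifnot(inherits(fit, "impress_fit"))
  fit$draws[which.max(fit$lp), ]
}

#' @rdname map_estimate
#' @export
posterior_mean <- function(fit) {
  stopifnot(inherits(fit, "impress_fit"))
  colMeans(fit$draws)
}

point_estimate <- function(fit, estimate) {
  switch(estimate, map = map_estimate(fit), mean = posterior_mean(fit))
}

# pull the zib/rating fixed effects out of a named estimate vector or an
# impress_params ground-truth object
estimate_components <- function(est) {
  if (inherits(est, "impress_params")) {
    return(list(
      alpha_bern = est$zib$alpha_bern, beta_bern = est$zib$beta_bern,
      alpha_beta = est$zib$alpha_beta, beta_beta = est$zib$beta_beta,
      beta_gaze = est$rating$beta_gaze, beta_trait = est$rating$beta_trait,
      cutpoints = est$rating$cutpoints
    ))
  }
  pick <- function(fmt, ...) unname(est[sprintf(fmt, ...)])
  list(
    alpha_bern = vapply(.areas, function(a) pick("bern_alpha.%s", a), 1),
    beta_bern = t(vapply(.areas, function(a) {
      vapply(.traits, function(l) pick("bern_beta.%s.%s", a, l), 1)
    }, numeric(5))),
    alpha_beta = vapply(.areas, function(a) pick("beta_alpha.%s", a), 1),
    beta_beta = t(vapply(.areas, function(a) {
      vapply(.traits, function(l) pick("beta_beta.%s.%s", a, l), 1)
    }, numeric(5))),
    beta_gaze = vapply(c(.areas, "eye:nose", "eye:mouth", "nose:mouth",
                         "eye:nose:mouth"),
                       function(g) pick("rating_gaze.%s", g), 1),
    beta_trait = vapply(.traits, function(l) pick("rating_trait.%s", l), 1),
    cutpoints = vapply(1:6, function(m) pick("cutpoint.%d", m), 1)
  )
}

resolve_trait_means <- function(object, trait_means) {
  if (!is.null(trait_means)) {
    stopifnot(length(trait_means) == 5L)
    return(setNames(as.numeric(trait_means), .traits))
  }
  if (inherits(object, "impress_fit") && !is.null(object$trait_means)) {
    return(object$trait_means)
  }
  setNames(rep(4, 5), .traits)  # trait-scale midpoint
}

#' Predictive gaze curves over a trait
#'
#' Sweeps one trait across the 1-7 scale with the other four fixed at
#' their sample means (random effects at 0, the population-level curve)
#' and reports, per area, the predicted looking probability (Bernoulli
#' component), the predicted gaze weight given looking (beta mean), and
#' their product (expected gaze weight) — the latter two cover both
#' readings of "predicted gaze weight".
#'
#' @param object An `impress_fit` from [fit_joint()] or an
#'   [impress_params] ground-truth object.
#' @param trait Trait to sweep: one of `big_five_traits()`.
#' @param grid Trait values to evaluate (default `seq(1, 7, by = 0.25)`).
#' @param trait_means Values for the non-swept traits; defaults to the
#'   fitted sample's trait means (or 4, the scale midpoint, for a
#'   parameter object).
#' @param estimate Point estimate: `"map"` (highest-posterior draw) or
#'   `"mean"`.
#' @return A tibble of class `gaze_curve`: `trait`, `value`, `area`,
#'   `probability`, `gaze_weight`, `expected_weight`.
#' @export
predict_gaze_curve <- function(object, trait, grid = seq(1, 7, by = 0.25),
                               trait_means = NULL,
                               estimate = c("map", "mean")) {
  estimate <- match.arg(estimate)
  if (!trait %in% .traits) {
    stop_data(sprintf("unknown trait '%s' (use one of %s)", trait,
                      paste(.traits, collapse = ", ")))
  }
  if (any(diff(grid) <= 0)) stop_config("`grid` must be strictly increasing")
  est <- if (inherits(object, "impress_fit")) {
    point_estimate(object, estimate)
  } else object
  cmp <- estimate_components(est)
  means <- resolve_trait_means(object, trait_means)
  p <- matrix(rep(means, each = length(grid)), length(grid), 5,
              dimnames = list(NULL, .traits))
  p[, trait] <- grid
  out <- purrr::map_dfr(seq_along(.areas), function(k) {
    q <- bern_prob(p, cmp$alpha_bern[k], cmp$beta_bern[k, ])
    mu <- beta_mean(p, cmp$alpha_beta[k], cmp$beta_beta[k, ])
    tibble(trait = trait, value = grid, area = .areas[k],
           probability = q, gaze_weight = mu, expected_weight = q * mu)
  })
  class(out) <- c("gaze_curve", class(out))
  out
}

#' Predictive rating curves over a trait
#'
#' Sweeps one trait across the 1-7 scale with the other traits at their
#' means and reports the ordered-logistic rating-category probabilities
#' and the expected rating at each grid value. Gaze covariates are fixed
#' either at their observed sample means or at the model-implied expected
#' weights (`q * mu`) for the trait values on the grid.
#'
#' @inheritParams predict_gaze_curve
#' @param gaze `"observed"` (sample means of the gaze weights; default) or
#'   `"model"` (model-implied expected weights at each grid value).
#' @return A tibble of class `rating_curve`: `trait`, `value`, `category`,
#'   `probability`, plus `expected` (expected rating, repeated within a
#'   grid value).
#' @export
predict_rating_curve <- function(object, trait, grid = seq(1, 7, by = 0.25),
                                 trait_means = NULL,
                                 estimate = c("map", "mean"),
                                 gaze = c("observed", "model")) {
  estimate <- match.arg(estimate); gaze <- match.arg(gaze)
  if (!trait %in% .traits) {
    stop_data(sprintf("unknown trait '%s'", trait))
  }
  est <- if (inherits(object, "impress_fit")) {
    point_estimate(object, estimate)
  } else object
  cmp <- estimate_components(est)
  means <- resolve_trait_means(object, trait_means)
  p <- matrix(rep(means, each = length(grid)), length(grid), 5,
              dimnames = list(NULL, .traits))
  p[, trait] <- grid
  G <- if (gaze == "observed") {
    if (!inherits(object, "impress_fit")) {
      stop_config("gaze = \"observed\" needs a fitted object")
    }
    gm <- colMeans(object$data[, paste0("g_", .areas)])
    matrix(rep(gm, each = length(grid)), length(grid), 3)
  } else {
    vapply(seq_along(.areas), function(k) {
      bern_prob(p, cmp$alpha_bern[k], cmp$beta_bern[k, ]) *
        beta_mean(p, cmp$alpha_beta[k], cmp$beta_beta[k, ])
    }, numeric(length(grid)))
  }
  eta <- rating_linpred(G, cmp$beta_gaze, p, cmp$beta_trait)
  pm <- rbind(ordered_logistic_pmf(eta, cmp$cutpoints))
  expected <- drop(pm %*% seq_len(ncol(pm)))
  out <- purrr::map_dfr(seq_len(ncol(pm)), function(m) {
    tibble(trait = trait, value = grid, category = m,
           probability = pm[, m], expected = expected)
  }) %>% arrange(.data$value, .data$category)
  class(out) <- c("rating_curve", class(out))
  out
}
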