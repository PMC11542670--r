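#' Inverse-logit (logistic) link
#'
#' @param eta Numeric vector of linear-predictor values.
#' @return Probabilities in (0, 1); saturates smoothly for extreme `eta`.
#' @export
#' @examples
#' inv_logit(0)    # 0.5
#' inv_logit(1)    # 0.7310586
inv_logit <- function(eta) plogis(eta)

check_traits <- function(p) {
  p <- rbind(p)
  if (ncol(p) != 5L) {
    stop_data("trait vector must have exactly 5 scores (agr, con, ext, neu, ope)")
  }
  p
}

#' Looking probability of the Bernoulli component
#'
#' Probability `q` that an observer looks at a facial area at least once,
#' as a logistic regression on the observer's five trait scores plus subject
#' and face random intercepts:
#' `q = inv_logit(alpha + sum_l beta[l] * p[l] + r_subject + r_face)`.
#'
#' @param p Trait scores: a length-5 vector or an n x 5 matrix
#'   (columns agr, con, ext, neu, ope on the raw 1-7 scale).
#' @param alpha Intercept.
#' @param beta Length-5 coefficient vector.
#' @param r_subject,r_face Random intercepts (default 0 gives the
#'   population-level value).
#' @return Probability vector.
#' @export
#' @examples
#' bern_prob(c(2, 4, 4, 4, 4), alpha = 1, beta = c(0.5, 0, 0, 0, 0))
bern_prob <- function(p, alpha, beta, r_subject = 0, r_face = 0) {
  p <- check_traits(p)
  unname(inv_logit(alpha + drop(p %*% beta) + r_subject + r_face))
}

#' Mean of the beta component
#'
#' Expected gaze weight `mu` of an area given that it was looked at; same
#' logistic-regression form as [bern_prob()].
#'
#' @inheritParams bern_prob
#' @return Mean vector in (0, 1).
#' @export
beta_mean <- function(p, alpha, beta, r_subject = 0, r_face = 0) {
  p <- check_traits(p)
  unname(inv_logit(alpha + drop(p %*% beta) + r_subject + r_face))
}

#' Beta shape parameters from mean and precision
#'
#' `a = phi * mu`, `b = phi * (1 - mu)`, so that `a + b = phi`.
#'
#' @param mu Mean in (0, 1).
#' @param phi Precision, > 0.
#' @return A list with components `a` and `b`.
#' @export
#' @examples
#' beta_shapes(0.2, 10)  # a = 2, b = 8
beta_shapes <- function(mu, phi) {
  if (any(mu <= 0 | mu >= 1)) stop_domain("`mu` must lie strictly in (0, 1)")
  if (any(phi <= 0)) stop_domain("`phi` must be > 0")
  list(a = phi * mu, b = phi * (1 - mu))
}

#' Zero-inflated beta log-density
#'
#' Mixture of a point mass at zero (probability `1 - q`) and a
#' `Beta(a, b)` on (0, 1) reached with probability `q`:
#' `log(1 - q)` when `g = 0`, otherwise `log(q) + dbeta(g, a, b, log = TRUE)`.
#' Structural impossibilities (a zero under `q = 1`, a positive value under
#' `q = 0`) return `-Inf` with a warning.
#'
#' @param g Gaze weight in `[0, 1)` (vectorized).
#' @param q Looking probability in `[0, 1]`.
#' @param a,b Beta shape parameters, > 0.
#' @return Log-density vector.
#' @export
#' @examples
#' zib_logdensity(0, q = 0.3, a = 2, b = 5)    # log(0.7)
#' zib_logdensity(0.5, q = 1, a = 1, b = 1)    # 0
zib_logdensity <- function(g, q, a, b) {
  if (any(g < 0 | g >= 1)) stop_domain("`g` must lie in [0, 1)")
  if (any(q < 0 | q > 1)) stop_domain("`q` must lie in [0, 1]")
  if (any(a <= 0) || any(b <= 0)) stop_domain("beta shapes must be > 0")
  n <- max(length(g), length(q), length(a), length(b))
  g <- rep_len(g, n); q <- rep_len(q, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- ifelse(g == 0, log1p(-q), log(q) + stats::dbeta(g, a, b, log = TRUE))
  if (any(is.infinite(out) & ((g == 0 & q == 1) | (g > 0 & q == 0)))) {
    warn("zero-probability branch hit: returning -Inf log-density")
  }
  out
}

check_cutpoints <- function(cutpoints) {
  if (length(cutpoints) < 1L || any(diff(cutpoints) <= 0)) {
    stop_domain("cutpoints must be strictly increasing")
  }
  invisible(cutpoints)
}

#' Ordered-logistic probability mass function
#'
#' Category probabilities for an ordinal outcome with `K = length(cutpoints)
#' + 1` categories: `P(1) = 1 - inv_logit(eta - c[1])`,
#' `P(m) = inv_logit(eta - c[m - 1]) - inv_logit(eta - c[m])`,
#' `P(K) = inv_logit(eta - c[K - 1])`.
#'
#' @param eta Linear predictor (vectorized).
#' @param cutpoints Strictly increasing thresholds, length `K - 1`.
#' @return For scalar `eta` a probability vector of length `K`; otherwise an
#'   `n x K` matrix with one row per value of `eta`.
#' @export
#' @examples
#' ordered_logistic_pmf(0, c(-1, 1))
ordered_logistic_pmf <- function(eta, cutpoints) {
  check_cutpoints(cutpoints)
  # S[, m] = P(Y > m) = inv_logit(eta - c_m); P(m) = S[, m - 1] - S[, m]
  S <- cbind(1, plogis(outer(eta, cutpoints, `-`)), 0)
  pr <- S[, -ncol(S), drop = FALSE] - S[, -1, drop = FALSE]
  if (length(eta) == 1L) drop(pr) else pr
}

#' Rating-model linear predictor
#'
#' Linear predictor of the ordered-logistic impression-rating model: three
#' gaze-weight main effects, the three pairwise products, the triple product,
#' five trait effects, and subject and face random intercepts.
#'
#' @param g Gaze weights: length-3 vector or n x 3 matrix
#'   (columns eye, nose, mouth).
#' @param beta_gaze Length-7 coefficients in the order eye, nose, mouth,
#'   eye:nose, eye:mouth, nose:mouth, eye:nose:mouth.
#' @inheritParams bern_prob
#' @param beta_trait Length-5 trait coefficients.
#' @return Numeric linear predictor.
#' @export
#' @examples
#' rating_linpred(c(0.2, 0.3, 0.5), beta_gaze = c(1, 1, 1, 2, 0, 0, 1),
#'                p = rep(0, 5), beta_trait = rep(0, 5))  # 1.15
rating_linpred <- function(g, beta_gaze, p, beta_trait,
                           r_subject = 0, r_face = 0) {
  g <- rbind(g)
  if (ncol(g) != 3L) stop_data("`g` must have 3 columns (eye, nose, mouth)")
  if (length(beta_gaze) != 7L) stop_data("`beta_gaze` must have length 7")
  p <- check_traits(p)
  X <- gaze_design(g)
  unname(drop(X %*% beta_gaze) + drop(p %*% beta_trait) +
           r_subject + r_face)
}

# 7-column gaze design: mains, pairwise products, triple product
gaze_design <- function(g) {
  cbind(g[, 1], g[, 2], g[, 3],
        g[, 1] * g[, 2], g[, 1] * g[, 3], g[, 2] * g[, 3],
        g[, 1] * g[, 2] * g[, 3])
}

#' Condition-model linear predictor
#'
#' Linear predictor of the between-condition rating model: a condition effect
#' (reference coding, `Free` fixed at 0) plus subject and face random
#' intercepts.
#'
#' @param condition Character vector of condition labels among
#'   `gaze_conditions()`.
#' @param beta_condition Named vector with entries `Eye`, `Nose`, `Mouth`.
#' @inheritParams bern_prob
#' @return Numeric linear predictor.
#' @export
#' @examples
#' condition_linpred("Eye", c(Eye = 0.4, Nose = 0, Mouth = 0))
condition_linpred <- function(condition, beta_condition,
                              r_subject = 0, r_face = 0) {
  if (!all(condition %in% .conditions)) {
    stop_data(sprintf("unknown condition label(s): %s",
                      paste(setdiff(condition, .conditions), collapse = ", ")))
  }
  b <- c(Free = 0, beta_condition[c("Eye", "Nose", "Mouth")])
  unname(b[condition]) + r_subject + r_face
}

# --- joint log-posterior (pure R reference) --------------------------------

# log prior of a fixed effect: Normal(0, sd 10)
lp_fixed <- function(x) sum(dnorm(x, 0, 10, log = TRUE))

# log prior of a random-effect scale: Gamma(10, 10); -Inf off support
lp_scale <- function(s) {
  if (any(s <= 0)) return(-Inf)
  sum(dgamma(s, shape = 10, rate = 10, log = TRUE))
}

# half-Normal(0, 10) prior for a beta precision
lp_phi <- function(phi) {
  if (any(phi <= 0)) return(-Inf)
  sum(dnorm(phi, 0, 10, log = TRUE) + log(2))
}

#' Joint log-posterior of the gaze and rating model
#'
#' Reference implementation of the full joint posterior density (up to a
#' constant) of the zero-inflated beta gaze model for the three areas plus
#' the ordered-logistic rating model: likelihood of every observation, plus
#' Normal(0, sd 10) priors on fixed effects and cutpoints (subject to
#' ordering), half-Normal(0, 10) priors on the beta precisions,
#' Gamma(10, 10) priors on random-effect scales, and Normal(0, sigma)
#' densities for the random intercepts. Used as the ground truth the
#' compiled sampler is tested against; the sampler itself evaluates the
#' same expression in C++.
#'
#' @param params An [impress_params] object (fixed effects and scales).
#' @param ranef Random effects: a list with matrices `bern_subject`,
#'   `beta_subject` (`n_subjects x 3`), `bern_face`, `beta_face`
#'   (`n_faces x 3`) and vectors `rating_subject`, `rating_face`.
#' @param data A study data frame as returned by [sim_study()]: one row per
#'   subject x face with columns `subject_id`, `stimulus_id`, `g_eye`,
#'   `g_nose`, `g_mouth`, `rating` and the five trait columns.
#' @return A scalar log-posterior; `-Inf` if any invariant (ordered
#'   cutpoints, positive scales and precisions) is violated.
#' @export
joint_log_posterior <- function(params, ranef, data) {
  stopifnot(inherits(params, "impress_params"))
  z <- params$zib; r <- params$rating
  if (any(z$phi <= 0) || any(diff(r$cutpoints) <= 0) ||
      any(unlist(z$sigma) <= 0) || any(unlist(r$sigma) <= 0)) {
    return(-Inf)
  }
  subj <- factor(data$subject_id, levels = unique(data$subject_id))
  face <- factor(data$stimulus_id, levels = unique(data$stimulus_id))
  si <- as.integer(subj); fi <- as.integer(face)
  p <- as.matrix(data[, .traits])
  G <- as.matrix(data[, paste0("g_", .areas)])

  lp <- 0
  for (k in 1:3) {
    q <- bern_prob(p, z$alpha_bern[k], z$beta_bern[k, ],
                   ranef$bern_subject[si, k], ranef$bern_face[fi, k])
    mu <- beta_mean(p, z$alpha_beta[k], z$beta_beta[k, ],
                    ranef$beta_subject[si, k], ranef$beta_face[fi, k])
    sh <- beta_shapes(mu, z$phi[k])
    lp <- lp + sum(zib_logdensity(G[, k], q, sh$a, sh$b))
  }
  eta <- rating_linpred(G, r$beta_gaze, p, r$beta_trait,
                        ranef$rating_subject[si], ranef$rating_face[fi])
  pm <- ordered_logistic_pmf(eta, r$cutpoints)
  lp <- lp + sum(log(pm[cbind(seq_along(eta), data$rating)]))

  lp <- lp +
    lp_fixed(c(z$alpha_bern, z$beta_bern, z$alpha_beta, z$beta_beta,
               r$beta_gaze, r$beta_trait, r$cutpoints)) +
    lp_phi(z$phi) +
    lp_scale(unlist(z$sigma)) + lp_scale(unlist(r$sigma))
  for (k in 1:3) {
    lp <- lp +
      sum(dnorm(ranef$bern_subject[, k], 0, z$sigma$bern_subject[k], log = TRUE)) +
      sum(dnorm(ranef$bern_face[, k], 0, z$sigma$bern_face[k], log = TRUE)) +
      sum(dnorm(ranef$beta_subject[, k], 0, z$sigma$beta_subject[k], log = TRUE)) +
      sum(dnorm(ranef$beta_face[, k], 0, z$sigma$beta_face[k], log = TRUE))
  }
  lp +
    sum(dnorm(ranef$rating_subject, 0, r$sigma$subject, log = TRUE)) +
    sum(dnorm(ranef$rating_face, 0, r$sigma$face, log = TRUE))
}
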