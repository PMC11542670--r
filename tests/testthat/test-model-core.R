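test_that("logistic link and linear predictors match closed forms", {
  expect_equal(inv_logit(0), 0.5)
  expect_lt(inv_logit(-50), 1e-20)
  expect_equal(inv_logit(1), 0.7310586, tolerance = 1e-6)

  p <- c(2, 4, 4, 4, 4)
  expect_equal(bern_prob(rep(0, 5), 0, rep(0, 5)), 0.5)
  expect_equal(bern_prob(p, alpha = 1, beta = c(0.5, 0, 0, 0, 0)),
               0.8807971, tolerance = 1e-6)
  # monotone in each coefficient-score product
  expect_gt(bern_prob(p, 1, c(0.6, 0, 0, 0, 0)),
            bern_prob(p, 1, c(0.5, 0, 0, 0, 0)))
  expect_equal(beta_mean(rep(0, 5), -1, rep(0, 5)), 0.2689414,
               tolerance = 1e-6)
  expect_error(bern_prob(c(1, 2, 3), 0, rep(0, 5)),
               class = "gazeimpress_data_error")
})

test_that("beta shapes follow the mean-precision parameterization", {
  expect_equal(beta_shapes(0.5, 2), list(a = 1, b = 1))
  expect_equal(beta_shapes(0.2, 10), list(a = 2, b = 8))
  sh <- beta_shapes(runif(20, 0.01, 0.99), 7)
  expect_equal(sh$a + sh$b, rep(7, 20))
  expect_error(beta_shapes(0, 1), class = "gazeimpress_domain_error")
  expect_error(beta_shapes(0.5, 0), class = "gazeimpress_domain_error")
})

test_that("zero-inflated beta log-density is correct and proper", {
  expect_equal(zib_logdensity(0, 0.3, 2, 5), log(0.7))
  expect_equal(zib_logdensity(0.5, 1, 1, 1), 0)
  expect_warning(out <- zib_logdensity(0, 1, 1, 1), "zero-probability")
  expect_identical(out, -Inf)

  # point mass + continuous part integrate to 1 (numeric quadrature)
  for (par in list(c(0.4, 2, 5), c(0.7, 0.5, 0.5), c(0.1, 8, 2))) {
    cont <- stats::integrate(function(x) {
      exp(zib_logdensity(x, par[1], par[2], par[3]))
    }, 0, 1, rel.tol = 1e-10)$value
    point <- exp(zib_logdensity(0, par[1], par[2], par[3]))
    expect_equal(point + cont, 1, tolerance = 1e-8)
  }
})

test_that("ordered-logistic pmf matches CDF differencing and closed form", {
  expect_equal(ordered_logistic_pmf(0, c(-1, 1)),
               c(0.2689414, 0.4621172, 0.2689414), tolerance = 1e-6)
  expect_gt(ordered_logistic_pmf(-50, c(-1, 0, 1))[1], 1 - 1e-12)
  expect_error(ordered_logistic_pmf(0, c(1, 1)),
               class = "gazeimpress_domain_error")

  set.seed(8)
  for (rep in 1:20) {
    eta <- rnorm(1, 0, 3)
    cc <- sort(rnorm(6, 0, 2))
    pm <- ordered_logistic_pmf(eta, cc)
    expect_equal(sum(pm), 1, tolerance = 1e-12)
    expect_true(all(pm >= 0))
    # brute-force differencing of the latent logistic CDF
    cdf <- c(plogis(cc, location = eta), 1)
    expect_equal(pm, diff(c(0, cdf)), tolerance = 1e-12)
  }
})

test_that("rating and condition linear predictors follow the model", {
  expect_equal(rating_linpred(c(0.2, 0.3, 0.5),
                              beta_gaze = c(1, 1, 1, 2, 0, 0, 1),
                              p = rep(0, 5), beta_trait = rep(0, 5)),
               1.15)
  # zero interactions reduce to the main-effects sum
  g <- c(0.1, 0.4, 0.2)
  expect_equal(rating_linpred(g, c(2, -1, 3, 0, 0, 0, 0), rep(0, 5),
                              rep(0, 5)),
               sum(g * c(2, -1, 3)))
  expect_equal(rating_linpred(rep(0, 3), rep(0, 7), rep(0, 5), rep(0, 5)), 0)

  expect_equal(condition_linpred("Free", c(Eye = 0.4, Nose = 1, Mouth = 2)), 0)
  expect_equal(condition_linpred("Eye", c(Eye = 0.4, Nose = 0, Mouth = 0)),
               0.4)
  expect_error(condition_linpred("Side", c(Eye = 0, Nose = 0, Mouth = 0)),
               class = "gazeimpress_data_error")
})

test_that("joint log posterior equals the independently summed blocks", {
  params <- default_true_params()
  study <- tiny_study(n_subjects = 2, n_faces = 2, seed = 31)
  data <- study$data
  ranef <- random_ranef(2, 2, seed = 5)

  # independent oracle: sum likelihood and prior terms with stats:: calls
  si <- match(data$subject_id, unique(data$subject_id))
  fi <- match(data$stimulus_id, unique(data$stimulus_id))
  p <- as.matrix(data[, big_five_traits()])
  G <- as.matrix(data[, c("g_eye", "g_nose", "g_mouth")])
  z <- params$zib; r <- params$rating
  oracle <- 0
  for (n in seq_len(nrow(data))) for (k in 1:3) {
    q <- plogis(z$alpha_bern[k] + sum(z$beta_bern[k, ] * p[n, ]) +
                ranef$bern_subject[si[n], k] + ranef$bern_face[fi[n], k])
    mu <- plogis(z$alpha_beta[k] + sum(z$beta_beta[k, ] * p[n, ]) +
                 ranef$beta_subject[si[n], k] + ranef$beta_face[fi[n], k])
    oracle <- oracle + if (G[n, k] == 0) log(1 - q) else {
      log(q) + stats::dbeta(G[n, k], z$phi[k] * mu, z$phi[k] * (1 - mu),
                            log = TRUE)
    }
  }
  for (n in seq_len(nrow(data))) {
    eta <- sum(r$beta_gaze * c(G[n, ], G[n, 1] * G[n, 2], G[n, 1] * G[n, 3],
                               G[n, 2] * G[n, 3], prod(G[n, ]))) +
      sum(r$beta_trait * p[n, ]) +
      ranef$rating_subject[si[n]] + ranef$rating_face[fi[n]]
    cdf <- c(0, plogis(r$cutpoints, location = eta), 1)
    oracle <- oracle + log(diff(cdf)[data$rating[n]])
  }
  oracle <- oracle +
    sum(dnorm(c(z$alpha_bern, z$beta_bern, z$alpha_beta, z$beta_beta,
                r$beta_gaze, r$beta_trait, r$cutpoints), 0, 10, log = TRUE)) +
    sum(dnorm(z$phi, 0, 10, log = TRUE) + log(2)) +
    sum(dgamma(c(unlist(z$sigma), unlist(r$sigma)), 10, 10, log = TRUE)) +
    sum(dnorm(ranef$bern_subject, 0,
              rep(z$sigma$bern_subject, each = 2), log = TRUE)) +
    sum(dnorm(ranef$bern_face, 0, rep(z$sigma$bern_face, each = 2),
              log = TRUE)) +
    sum(dnorm(ranef$beta_subject, 0, rep(z$sigma$beta_subject, each = 2),
              log = TRUE)) +
    sum(dnorm(ranef$beta_face, 0, rep(z$sigma$beta_face, each = 2),
              log = TRUE)) +
    sum(dnorm(ranef$rating_subject, 0, r$sigma$subject, log = TRUE)) +
    sum(dnorm(ranef$rating_face, 0, r$sigma$face, log = TRUE))

  expect_equal(joint_log_posterior(params, ranef, data), unname(oracle),
               tolerance = 1e-10)

  # invariant violations yield -Inf
  bad <- params
  bad$rating$cutpoints <- rev(bad$rating$cutpoints)
  expect_identical(joint_log_posterior(bad, ranef, data), -Inf)
})

test_that("compiled posterior matches the reference and its own gradient", {
  params <- default_true_params()
  study <- tiny_study(n_subjects = 4, n_faces = 3, seed = 13)
  info <- gazeimpress:::joint_model_data(study$data)
  cpp <- info$cpp
  cpp$P <- sweep(cpp$P, 2, -info$p_bar)     # undo centering
  cpp$Xord <- sweep(cpp$Xord, 2, -info$x_bar)
  cpp$p_bar <- rep(0, 5)
  cpp$xo_bar <- rep(0, ncol(cpp$Xord))
  L <- gazeimpress:::param_layout(TRUE, cpp$NS, cpp$NF, cpp$K,
                                  ncol(cpp$Xord))
  ranef <- random_ranef(4, 3, seed = 21)
  par <- pack_params(params, ranef, L)
  res <- gazeimpress:::cpp_logpost_grad(par, cpp, jacobian = FALSE)
  expect_equal(res$lp, joint_log_posterior(params, ranef, study$data),
               tolerance = 1e-10)

  # analytic gradient vs central finite differences (sampling scale)
  cppc <- info$cpp
  full <- gazeimpress:::cpp_logpost_grad(par, cppc, jacobian = TRUE)
  eps <- 1e-5
  idx <- withr::with_seed(3, sample(L$D, 30))
  fd <- vapply(idx, function(d) {
    up <- par; up[d] <- up[d] + eps
    dn <- par; dn[d] <- dn[d] - eps
    (gazeimpress:::cpp_logpost_grad(up, cppc, TRUE)$lp -
       gazeimpress:::cpp_logpost_grad(dn, cppc, TRUE)$lp) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - full$grad[idx]) / pmax(1, abs(fd))), 1e-4)
})

test_that("changing one observation only changes its own contribution", {
  params <- default_true_params()
  study <- tiny_study(n_subjects = 3, n_faces = 3, seed = 17)
  data <- study$data
  ranef <- random_ranef(3, 3, seed = 23)
  base <- joint_log_posterior(params, ranef, data)
  mod <- data
  mod$rating[5] <- if (mod$rating[5] == 7) 1L else mod$rating[5] + 1L
  delta <- joint_log_posterior(params, ranef, mod) - base
  # recompute just row 5's rating term by hand
  r <- params$rating
  p5 <- as.numeric(mod[5, big_five_traits()])
  g5 <- as.numeric(mod[5, c("g_eye", "g_nose", "g_mouth")])
  si <- match(mod$subject_id[5], unique(mod$subject_id))
  fi <- match(mod$stimulus_id[5], unique(mod$stimulus_id))
  eta <- rating_linpred(g5, r$beta_gaze, p5, r$beta_trait,
                        ranef$rating_subject[si], ranef$rating_face[fi])
  pm <- ordered_logistic_pmf(eta, r$cutpoints)
  expect_equal(delta, log(pm[mod$rating[5]]) - log(pm[data$rating[5]]),
               tolerance = 1e-10)
})
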