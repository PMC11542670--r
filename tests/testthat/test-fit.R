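test_that("sampler configuration is validated", {
  cfg <- mcmc_config()
  expect_equal(cfg$chains, 4)
  expect_equal(cfg$iterations, 2000)
  expect_equal(cfg$warmup, 1000)
  expect_equal(cfg$thin, 1)
  expect_error(mcmc_config(chains = 0), class = "gazeimpress_config_error")
  expect_error(mcmc_config(iterations = 500, warmup = 500),
               class = "gazeimpress_config_error")
  expect_error(mcmc_config(thin = 0), class = "gazeimpress_config_error")
})

test_that("the joint fit returns complete, reproducible draws", {
  study <- tiny_study(seed = 101)
  fit1 <- quiet_fit(study$data, quick_config(seed = 5))
  fit2 <- quiet_fit(study$data, quick_config(seed = 5))
  expect_identical(fit1$draws, fit2$draws)  # same seed, same draws
  fit3 <- quiet_fit(study$data, quick_config(seed = 6))
  expect_false(identical(fit1$draws, fit3$draws))

  # chains x kept draws
  expect_equal(nrow(fit1$draws), 2 * 300)
  expect_equal(sort(unique(fit1$chain)), 1:2)

  # every declared parameter is covered: fixed effects, precisions,
  # cutpoints, random effects and their scales
  terms <- colnames(fit1$draws)
  expect_length(grep("^bern_alpha|^beta_alpha", terms), 6)
  expect_length(grep("^bern_beta|^beta_beta", terms), 30)
  expect_length(grep("^phi\\.", terms), 3)
  expect_length(grep("^rating_gaze", terms), 7)
  expect_length(grep("^rating_trait", terms), 5)
  expect_length(grep("^cutpoint", terms), 6)
  expect_length(grep("^ranef_bern_subject", terms), 3 * 10)
  expect_length(grep("^ranef_beta_face", terms), 3 * 5)
  expect_length(grep("^ranef_rating", terms), 15)
  expect_length(grep("^sigma_", terms), 14)

  # invariants of the draws themselves
  expect_true(all(fit1$draws[, grep("^phi|^sigma", terms)] > 0))
  cuts <- fit1$draws[, sprintf("cutpoint.%d", 1:6)]
  expect_true(all(apply(cuts, 1, function(x) all(diff(x) > 0))))

  # thinning halves the retained draws
  fit_thin <- quiet_fit(study$data, mcmc_config(chains = 2,
                                                iterations = 600,
                                                warmup = 300, thin = 2,
                                                seed = 5))
  expect_equal(nrow(fit_thin$draws), 2 * 150)
})

test_that("broom-style accessors summarise a fit", {
  study <- tiny_study(seed = 102)
  fit <- quiet_fit(study$data, quick_config(seed = 2))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat",
                    "significant") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(study$data))
  expect_equal(gl$draws, 600)
  expect_equal(gl$n_subjects, 10)
  mp <- map_estimate(fit)
  expect_equal(names(mp), colnames(fit$draws))
})

test_that("condition fits report reference-coded contrasts", {
  params <- default_true_params()
  params$condition$beta[] <- c(2.5, 0, 0)  # strong Eye effect
  data <- sim_condition_study(c(Free = 20, Eye = 20, Nose = 20), 6,
                              params, seed = 3)
  fit <- suppressWarnings(fit_condition_model(data, quick_config(seed = 4)))
  ct <- condition_contrasts(fit)
  expect_setequal(ct$contrast, c("Eye-Free", "Nose-Free"))
  # the reference is never contrasted with itself
  expect_false("Free-Free" %in% ct$contrast)
  eye <- ct[ct$contrast == "Eye-Free", ]
  expect_true(eye$significant)
  expect_gt(eye$mean, 0)
  # a condition contrasted with itself is identically zero on every draw
  self_contrast <- fit$draws[, "condition.Eye"] - fit$draws[, "condition.Eye"]
  expect_true(all(self_contrast == 0))
  expect_error(fit_condition_model(data[data$condition == "Eye", ],
                                   quick_config()),
               class = "gazeimpress_config_error")
})

test_that("posterior means agree with an independent Gibbs sampler", {
  skip_if_not_installed("rjags")
  study <- tiny_study(n_subjects = 12, n_faces = 5, seed = 77)
  fit <- quiet_fit(study$data,
                   mcmc_config(chains = 2, iterations = 1500, warmup = 500,
                               seed = 9))
  data <- study$data
  subjects <- unique(data$subject_id); faces <- unique(data$stimulus_id)
  si <- match(data$subject_id, subjects); fi <- match(data$stimulus_id, faces)
  P <- as.matrix(data[match(subjects, data$subject_id), big_five_traits()])
  G <- as.matrix(data[, c("g_eye", "g_nose", "g_mouth")])
  pos <- which(G > 0, arr.ind = TRUE)
  jags_data <- list(
    N = nrow(data), NS = length(subjects), NF = length(faces), K = 7,
    si = si, fi = fi, p = P, G = G, z = matrix(as.integer(G > 0), nrow(G), 3),
    Y = data$rating, Npos = nrow(pos), Gpos = G[pos], ak = pos[, 2],
    psi = si[pos[, 1]], pfi = fi[pos[, 1]]
  )
  model <- "model {
    for (n in 1:N) { for (k in 1:3) {
      z[n,k] ~ dbern(q[n,k])
      logit(q[n,k]) <- aZ[k] + inprod(bZ[k,1:5], p[si[n],1:5]) +
                       rZs[si[n],k] + rZf[fi[n],k]
    } }
    for (m in 1:Npos) {
      Gpos[m] ~ dbeta(phi[ak[m]]*mu[m], phi[ak[m]]*(1-mu[m]))
      logit(mu[m]) <- aB[ak[m]] + inprod(bB[ak[m],1:5], p[psi[m],1:5]) +
                      rBs[psi[m],ak[m]] + rBf[pfi[m],ak[m]]
    }
    for (n in 1:N) {
      eta[n] <- inprod(bRG[1:3], G[n,1:3]) + bRG[4]*G[n,1]*G[n,2] +
                bRG[5]*G[n,1]*G[n,3] + bRG[6]*G[n,2]*G[n,3] +
                bRG[7]*G[n,1]*G[n,2]*G[n,3] +
                inprod(bRP[1:5], p[si[n],1:5]) + rRs[si[n]] + rRf[fi[n]]
      Y[n] ~ dcat(pr[n,1:K])
      pr[n,1] <- 1 - ilogit(eta[n]-cc[1])
      for (m in 2:(K-1)) { pr[n,m] <- ilogit(eta[n]-cc[m-1]) - ilogit(eta[n]-cc[m]) }
      pr[n,K] <- ilogit(eta[n]-cc[K-1])
    }
    for (m in 1:(K-1)) { c0[m] ~ dnorm(0, 0.01) }
    cc <- sort(c0)
    for (k in 1:3) {
      aZ[k] ~ dnorm(0, 0.01); aB[k] ~ dnorm(0, 0.01)
      phi[k] ~ dnorm(0, 0.01) T(0,)
      for (l in 1:5) { bZ[k,l] ~ dnorm(0, 0.01); bB[k,l] ~ dnorm(0, 0.01) }
      sZs[k] ~ dgamma(10,10); sZf[k] ~ dgamma(10,10)
      sBs[k] ~ dgamma(10,10); sBf[k] ~ dgamma(10,10)
      for (i in 1:NS) { rZs[i,k] ~ dnorm(0, 1/(sZs[k]*sZs[k]))
                        rBs[i,k] ~ dnorm(0, 1/(sBs[k]*sBs[k])) }
      for (j in 1:NF) { rZf[j,k] ~ dnorm(0, 1/(sZf[k]*sZf[k]))
                        rBf[j,k] ~ dnorm(0, 1/(sBf[k]*sBf[k])) }
    }
    for (g in 1:7) { bRG[g] ~ dnorm(0, 0.01) }
    for (l in 1:5) { bRP[l] ~ dnorm(0, 0.01) }
    sRs ~ dgamma(10,10); sRf ~ dgamma(10,10)
    for (i in 1:NS) { rRs[i] ~ dnorm(0, 1/(sRs*sRs)) }
    for (j in 1:NF) { rRf[j] ~ dnorm(0, 1/(sRf*sRf)) }
  }"
  jm <- rjags::jags.model(
    textConnection(model), data = jags_data, n.chains = 2, n.adapt = 500,
    quiet = TRUE,
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1,
                      c0 = seq(-2.5, 2.5, by = 1)),
                 list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2,
                      c0 = seq(-2.5, 2.5, by = 1))))
  sm <- rjags::coda.samples(jm, c("aZ", "bZ", "bB", "bRP", "phi"),
                            n.iter = 1000)
  jags_means <- colMeans(as.matrix(sm))

  ours <- posterior_mean(fit)
  # compare parameters on which the Gibbs oracle itself mixes well at
  # this run length: Bernoulli and rating slopes, and the precisions.
  # (Intercepts of near-saturated areas are prior-dominated, and the
  # beta-block slopes mix an order of magnitude more slowly under slice
  # sampling — their Gibbs estimates drift toward the HMC values only in
  # much longer runs.)
  pairs <- rbind(
    c("bern_beta.eye.ext", "bZ[1,3]"), c("bern_beta.nose.ope", "bZ[2,5]"),
    c("bern_beta.mouth.neu", "bZ[3,4]"),
    c("rating_trait.agr", "bRP[1]"), c("rating_trait.ope", "bRP[5]")
  )
  for (i in seq_len(nrow(pairs))) {
    # allow for Monte-Carlo error of both samplers, scaled by how wide
    # the (common) posterior is
    tol <- max(0.2, 0.5 * sd(fit$draws[, pairs[i, 1]]))
    expect_lt(abs(ours[pairs[i, 1]] - jags_means[pairs[i, 2]]), tol,
              label = sprintf("|HMC - JAGS| for %s", pairs[i, 1]))
  }
  for (k in 1:3) {
    expect_equal(unname(ours[sprintf("phi.%s", aoi_areas()[k])]),
                 unname(jags_means[sprintf("phi[%d]", k)]),
                 tolerance = 0.15 * unname(jags_means[sprintf("phi[%d]", k)]))
  }
})

test_that("non-convergence is flagged, not silently accepted", {
  study <- tiny_study(n_subjects = 4, n_faces = 3, seed = 55)
  expect_warning(
    fit_joint(study$data, mcmc_config(chains = 2, iterations = 20,
                                      warmup = 10, seed = 1)),
    class = "gazeimpress_convergence_warning")
  fit <- suppressWarnings(
    fit_joint(study$data, mcmc_config(chains = 2, iterations = 20,
                                      warmup = 10, seed = 1)))
  expect_false(convergence_ok(fit))
  expect_false(glance(fit)$converged)
})
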