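# shared fixtures, all generated in code

# small study for fast fitting tests
tiny_study <- function(n_subjects = 10, n_faces = 5, seed = 42,
                       params = default_true_params()) {
  sim_study(n_subjects = n_subjects, n_faces_per_task = n_faces,
            params = params, seed = seed)
}

quick_config <- function(chains = 2, iterations = 600, warmup = 300,
                         seed = 1) {
  mcmc_config(chains = chains, iterations = iterations, warmup = warmup,
              seed = seed)
}

quiet_fit <- function(data, config, ...) {
  suppressWarnings(fit_joint(data, config, ...))
}

# small mask on a small canvas for preprocessing tests
tiny_mask <- function(canvas = c(80, 100)) {
  layout <- list(
    eye = list(list(cx = 20, cy = 30, rx = 10, ry = 6),
               list(cx = 60, cy = 30, rx = 10, ry = 6)),
    nose = list(list(cx = 40, cy = 55, rx = 8, ry = 8)),
    mouth = list(list(cx = 40, cy = 80, rx = 14, ry = 6))
  )
  sim_masks(canvas, layout, stimulus_id = "tiny")
}

# map an impress_params + random-effect list onto the unconstrained
# parameter vector of the compiled model (layout must match src/)
pack_params <- function(params, ranef, L) {
  par <- numeric(L$D)
  par[L$aZ] <- params$zib$alpha_bern
  par[L$bZ] <- as.vector(t(params$zib$beta_bern))
  par[L$aB] <- params$zib$alpha_beta
  par[L$bB] <- as.vector(t(params$zib$beta_beta))
  par[L$phi] <- log(params$zib$phi)
  par[L$bOrd] <- c(params$rating$beta_gaze, params$rating$beta_trait)
  cc <- params$rating$cutpoints
  par[L$thc] <- c(cc[1], log(diff(cc)))
  NS <- L$NS; NF <- L$NF
  for (k in 1:3) {
    par[L$rZs[(k - 1) * NS + 1:NS]] <- ranef$bern_subject[, k]
    par[L$rZf[(k - 1) * NF + 1:NF]] <- ranef$bern_face[, k]
    par[L$rBs[(k - 1) * NS + 1:NS]] <- ranef$beta_subject[, k]
    par[L$rBf[(k - 1) * NF + 1:NF]] <- ranef$beta_face[, k]
  }
  par[L$rRs] <- ranef$rating_subject
  par[L$rRf] <- ranef$rating_face
  par[L$sZs] <- log(params$zib$sigma$bern_subject)
  par[L$sZf] <- log(params$zib$sigma$bern_face)
  par[L$sBs] <- log(params$zib$sigma$beta_subject)
  par[L$sBf] <- log(params$zib$sigma$beta_face)
  par[L$sRs] <- log(params$rating$sigma$subject)
  par[L$sRf] <- log(params$rating$sigma$face)
  par
}

random_ranef <- function(NS, NF, seed = 7, sd = 0.3) {
  withr::with_seed(seed, list(
    bern_subject = matrix(rnorm(NS * 3, 0, sd), NS, 3),
    bern_face = matrix(rnorm(NF * 3, 0, sd), NF, 3),
    beta_subject = matrix(rnorm(NS * 3, 0, sd), NS, 3),
    beta_face = matrix(rnorm(NF * 3, 0, sd), NF, 3),
    rating_subject = rnorm(NS, 0, sd),
    rating_face = rnorm(NF, 0, sd)
  ))
}
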