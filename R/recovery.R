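# Replicate simulation studies: parameter recovery, null calibration and
# condition-contrast recovery against known ground truth.

#' True fixed-effect values of a parameter set
#'
#' Named vector of the ground-truth fixed effects (intercepts and trait
#' coefficients of the Bernoulli and beta components, gaze and trait
#' coefficients of the rating model) keyed by the posterior draw names
#' used by [fit_joint()].
#'
#' @param params An [impress_params] object.
#' @return Named numeric vector (48 fixed effects).
#' @export
true_fixed_effects <- function(params) {
  validate_params(params)
  z <- params$zib; r <- params$rating
  out <- c()
  for (k in 1:3) {
    out[paste0("bern_alpha.", .areas[k])] <- z$alpha_bern[k]
    out[paste0("beta_alpha.", .areas[k])] <- z$alpha_beta[k]
    for (l in 1:5) {
      out[paste0("bern_beta.", .areas[k], ".", .traits[l])] <- z$beta_bern[k, l]
      out[paste0("beta_beta.", .areas[k], ".", .traits[l])] <- z$beta_beta[k, l]
    }
  }
  gnames <- c(.areas, "eye:nose", "eye:mouth", "nose:mouth", "eye:nose:mouth")
  for (g in 1:7) out[paste0("rating_gaze.", gnames[g])] <- r$beta_gaze[g]
  for (l in 1:5) out[paste0("rating_trait.", .traits[l])] <- r$beta_trait[l]
  out
}

#' Parameter-recovery and null-calibration simulation studies
#'
#' `run_recovery_study()` simulates `n_reps` independent studies from known
#' parameters, fits the joint model to each with a reduced MCMC
#' configuration, and records, for every true fixed effect, whether the
#' 95% HDI covered it, whether the posterior mean had the right sign, and
#' whether the HDI excluded zero. With the ground-truth defaults this is a
#' coverage check (the HDIs should contain the truth about 95% of the
#' time); with [null_true_params()] it is a null-calibration check (HDIs
#' should rarely exclude zero).
#'
#' @param n_reps Number of replicate studies.
#' @param n_subjects,n_faces Study size per replicate.
#' @param params Ground-truth [impress_params].
#' @param mcmc An [mcmc_config()]; the default is the reduced
#'   2-chain, 500 warmup + 500 kept configuration used for simulation
#'   studies.
#' @param seed Integer seed governing every replicate.
#' @return A tibble with one row per replicate x fixed effect: `rep`,
#'   `term`, `true`, `estimate`, `conf.low`, `conf.high`, `covered`,
#'   `sign_correct`, `excludes_zero`, `converged`.
#' @export
run_recovery_study <- function(n_reps = 20, n_subjects = 34, n_faces = 10,
                               params = default_true_params(),
                               mcmc = mcmc_config(chains = 2,
                                                  iterations = 1000,
                                                  warmup = 500),
                               seed = 1) {
  truth <- true_fixed_effects(params)
  purrr::map_dfr(seq_len(n_reps), function(rep) {
    rep_seed <- child_seed(seed, paste0("recovery", rep))
    study <- sim_study(n_subjects = n_subjects, n_faces_per_task = n_faces,
                       params = params, seed = rep_seed)
    cfg <- mcmc
    cfg$seed <- child_seed(rep_seed, "fit")
    fit <- suppressWarnings(fit_joint(study$data, cfg))
    td <- tidy(fit) %>% filter(.data$term %in% names(truth))
    td %>%
      mutate(rep = rep, true = truth[.data$term],
             covered = .data$conf.low <= .data$true &
               .data$true <= .data$conf.high,
             sign_correct = sign(.data$estimate) == sign(.data$true),
             excludes_zero = .data$conf.low > 0 | .data$conf.high < 0,
             converged = convergence_ok(fit)) %>%
      select("rep", "term", "true", "estimate", "conf.low", "conf.high",
             "covered", "sign_correct", "excludes_zero", "converged")
  })
}

#' Condition-contrast recovery study
#'
#' Simulates `n_reps` between-condition studies from known condition
#' effects, fits the condition model with a reduced configuration, and
#' records whether each contrast's 95% HDI excludes zero. With the
#' ground-truth default (`Eye = 0.5`, others 0) a successful replicate
#' detects the Eye-Free contrast and does not flag the null Nose-Free
#' contrast.
#'
#' @inheritParams run_recovery_study
#' @param n_per_condition Named subject counts per condition.
#' @param n_faces Faces rated by every subject.
#' @return A tibble with one row per replicate x contrast: `rep`,
#'   `contrast`, `true`, `mean`, `lower`, `upper`, `significant`.
#' @export
run_condition_recovery <- function(n_reps = 20,
                                   n_per_condition = c(Free = 34, Eye = 34,
                                                       Nose = 34, Mouth = 35),
                                   n_faces = 10,
                                   params = default_true_params(),
                                   mcmc = mcmc_config(chains = 2,
                                                      iterations = 1000,
                                                      warmup = 500),
                                   seed = 1) {
  truth <- params$condition$beta
  purrr::map_dfr(seq_len(n_reps), function(rep) {
    rep_seed <- child_seed(seed, paste0("condition", rep))
    data <- sim_condition_study(n_per_condition, n_faces, params,
                                seed = rep_seed)
    cfg <- mcmc
    cfg$seed <- child_seed(rep_seed, "fit")
    fit <- suppressWarnings(fit_condition_model(data, cfg))
    condition_contrasts(fit) %>%
      mutate(rep = rep,
             true = truth[sub("-Free$", "", .data$contrast)]) %>%
      select("rep", "contrast", "true", "mean", "lower", "upper",
             "significant")
  })
}
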