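#' MCMC configuration
#'
#' Sampler settings. The defaults reproduce the reference analysis: 4
#' chains of 2000 iterations each with 1000 warmup and no thinning, i.e.
#' 4000 retained draws.
#'
#' @param chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param iterations Total iterations per chain (warmup included).
#' @param warmup Warmup iterations per chain (adaptation; discarded).
#' @param thin Keep every `thin`-th draw.
#' @param seed Integer seed; all chains derive their streams from it.
#' @return An object of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(chains = 2, iterations = 1000, warmup = 500, seed = 1)
mcmc_config <- function(chains = 4, iterations = 2000, warmup = 1000,
                        thin = 1, seed = 1) {
  if (!is_count(chains, 1L)) stop_config("`chains` must be a count >= 1")
  if (!is_count(iterations, 2L) || !is_count(warmup, 1L) ||
      warmup >= iterations) {
    stop_config("`warmup` must be a count below `iterations`")
  }
  if (!is_count(thin, 1L)) stop_config("`thin` must be a count >= 1")
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, seed = seed),
            class = "mcmc_config")
}

# mirror of the C++ parameter layout; offsets are 1-based starts
param_layout <- function(zib, NS, NF, K, Pord) {
  off <- 0L
  take <- function(n) {
    out <- off + seq_len(n)
    off <<- off + n
    out
  }
  L <- list(zib = zib, NS = NS, NF = NF, K = K, Pord = Pord)
  if (zib) {
    L$aZ <- take(3L); L$bZ <- take(15L); L$aB <- take(3L); L$bB <- take(15L)
    L$phi <- take(3L)
  }
  L$bOrd <- take(Pord); L$thc <- take(K - 1L)
  if (zib) {
    L$rZs <- take(3L * NS); L$rZf <- take(3L * NF)
    L$rBs <- take(3L * NS); L$rBf <- take(3L * NF)
  }
  L$rRs <- take(NS); L$rRf <- take(NF)
  if (zib) {
    L$sZs <- take(3L); L$sZf <- take(3L); L$sBs <- take(3L); L$sBf <- take(3L)
  }
  L$sRs <- take(1L); L$sRf <- take(1L)
  L$D <- off
  L
}

check_study_data <- function(data) {
  need <- c("subject_id", "stimulus_id", paste0("g_", .areas), "rating",
            .traits)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop_data(sprintf("study data lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if (any(!data$rating %in% 1:7)) stop_data("ratings must lie in 1..7")
  invisible(data)
}

# assemble the C++ data list for the joint model; covariates are centered
# for sampler conditioning and draws are un-centered afterwards
joint_model_data <- function(data) {
  check_study_data(data)
  subjects <- unique(data$subject_id)
  faces <- unique(data$stimulus_id)
  si <- match(data$subject_id, subjects)
  fi <- match(data$stimulus_id, faces)
  P <- as.matrix(data[, .traits])[match(subjects, data$subject_id), , drop = FALSE]
  p_bar <- colMeans(P)
  G <- as.matrix(data[, paste0("g_", .areas)])
  Xord <- cbind(gaze_design(G), P[si, , drop = FALSE])
  x_bar <- colMeans(Xord)
  list(
    cpp = list(include_zib = TRUE, N = nrow(data), NS = length(subjects),
               NF = length(faces), K = 7L, si = si - 1L, fi = fi - 1L,
               P = sweep(P, 2, p_bar), G = G,
               Z = matrix(as.integer(G > 0), nrow(G), 3),
               lG = ifelse(G > 0, log(G), 0),
               l1G = ifelse(G > 0, log1p(-G), 0),
               Y = as.integer(data$rating),
               Xord = sweep(Xord, 2, x_bar),
               p_bar = p_bar, xo_bar = x_bar),
    subjects = subjects, faces = faces, p_bar = p_bar, x_bar = x_bar,
    task = if ("task" %in% names(data)) unique(data$task)[1] else NA_character_
  )
}

condition_model_data <- function(data, reference = "Free") {
  need <- c("subject_id", "stimulus_id", "condition", "rating")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop_data(sprintf("condition data lacks column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  conds <- intersect(.conditions, unique(data$condition))
  if (length(conds) < 2L) {
    stop_config("condition model needs at least two conditions")
  }
  if (!reference %in% conds) {
    stop_config(sprintf("reference condition '%s' not present", reference))
  }
  others <- setdiff(conds, reference)
  subjects <- unique(data$subject_id)
  faces <- unique(data$stimulus_id)
  si <- match(data$subject_id, subjects)
  fi <- match(data$stimulus_id, faces)
  Xord <- vapply(others, function(d) as.numeric(data$condition == d),
                 numeric(nrow(data)))
  Xord <- matrix(Xord, nrow(data), length(others),
                 dimnames = list(NULL, others))
  x_bar <- colMeans(Xord)
  list(
    cpp = list(include_zib = FALSE, N = nrow(data), NS = length(subjects),
               NF = length(faces), K = 7L, si = si - 1L, fi = fi - 1L,
               P = matrix(0, length(subjects), 5), G = matrix(0, 0, 3),
               Z = matrix(0L, 0, 3), Y = as.integer(data$rating),
               Xord = sweep(Xord, 2, x_bar),
               p_bar = rep(0, 5), xo_bar = x_bar),
    subjects = subjects, faces = faces, x_bar = x_bar,
    reference = reference, others = others
  )
}

# default unconstrained initial point (before per-chain jitter)
init_point <- function(L) {
  init <- numeric(L$D)
  init[L$thc] <- c(-2, rep(log(0.8), L$K - 2L))
  if (L$zib) init[L$phi] <- log(5)
  init
}

run_chains <- function(cpp_data, config, init_step = 0.05) {
  L <- param_layout(cpp_data$include_zib, cpp_data$NS, cpp_data$NF,
                    cpp_data$K, ncol(cpp_data$Xord))
  kept <- config$iterations - config$warmup
  chains <- lapply(seq_len(config$chains), function(ch) {
    with_seed(child_seed(config$seed, paste0("chain", ch)), {
      init <- init_point(L) + rnorm(L$D, 0, 0.1)
      cpp_hmc_sample(cpp_data, init, config$warmup, kept,
                     init_step = init_step)
    })
  })
  keep_idx <- seq(1L, kept, by = config$thin)
  list(
    layout = L,
    draws = lapply(chains, function(x) x$draws[keep_idx, , drop = FALSE]),
    lp = lapply(chains, function(x) x$lp[keep_idx]),
    accept = vapply(chains, `[[`, numeric(1), "accept_rate"),
    divergences = sum(vapply(chains, `[[`, numeric(1), "divergences"))
  )
}

# transform one chain's unconstrained draws to named constrained draws on
# the raw covariate scale
constrain_joint <- function(U, L, info) {
  n <- nrow(U)
  p_bar <- info$p_bar; x_bar <- info$x_bar
  cols <- list()
  bZ <- U[, L$bZ, drop = FALSE]; bB <- U[, L$bB, drop = FALSE]
  # beta_bern column order is row-major (area, trait)
  for (k in 1:3) {
    sel <- (k - 1) * 5 + 1:5
    cols[[paste0("bern_alpha.", .areas[k])]] <-
      U[, L$aZ[k]] - bZ[, sel, drop = FALSE] %*% p_bar
    cols[[paste0("beta_alpha.", .areas[k])]] <-
      U[, L$aB[k]] - bB[, sel, drop = FALSE] %*% p_bar
    for (l in 1:5) {
      cols[[paste0("bern_beta.", .areas[k], ".", .traits[l])]] <- bZ[, sel[l]]
      cols[[paste0("beta_beta.", .areas[k], ".", .traits[l])]] <- bB[, sel[l]]
    }
    cols[[paste0("phi.", .areas[k])]] <- exp(U[, L$phi[k]])
  }
  gnames <- c(.areas, "eye:nose", "eye:mouth", "nose:mouth", "eye:nose:mouth")
  for (g in 1:7) cols[[paste0("rating_gaze.", gnames[g])]] <- U[, L$bOrd[g]]
  for (l in 1:5) cols[[paste0("rating_trait.", .traits[l])]] <- U[, L$bOrd[7 + l]]
  cc <- t(apply(U[, L$thc, drop = FALSE], 1, function(th) {
    cumsum(c(th[1], exp(th[-1])))
  }))
  shift <- U[, L$bOrd, drop = FALSE] %*% x_bar
  for (m in 1:(L$K - 1)) cols[[paste0("cutpoint.", m)]] <- cc[, m] + shift
  ranef_blocks <- list(bern_subject = list(L$rZs, info$subjects),
                       bern_face = list(L$rZf, info$faces),
                       beta_subject = list(L$rBs, info$subjects),
                       beta_face = list(L$rBf, info$faces))
  for (bn in names(ranef_blocks)) {
    idx <- ranef_blocks[[bn]][[1]]; lev <- ranef_blocks[[bn]][[2]]
    nl <- length(lev)
    for (k in 1:3) for (t in seq_len(nl)) {
      cols[[paste0("ranef_", bn, ".", .areas[k], ".", lev[t])]] <-
        U[, idx[(k - 1) * nl + t]]
    }
  }
  for (t in seq_along(info$subjects)) {
    cols[[paste0("ranef_rating_subject.", info$subjects[t])]] <- U[, L$rRs[t]]
  }
  for (t in seq_along(info$faces)) {
    cols[[paste0("ranef_rating_face.", info$faces[t])]] <- U[, L$rRf[t]]
  }
  for (k in 1:3) {
    cols[[paste0("sigma_bern_subject.", .areas[k])]] <- exp(U[, L$sZs[k]])
    cols[[paste0("sigma_bern_face.", .areas[k])]] <- exp(U[, L$sZf[k]])
    cols[[paste0("sigma_beta_subject.", .areas[k])]] <- exp(U[, L$sBs[k]])
    cols[[paste0("sigma_beta_face.", .areas[k])]] <- exp(U[, L$sBf[k]])
  }
  cols[["sigma_rating_subject"]] <- exp(U[, L$sRs])
  cols[["sigma_rating_face"]] <- exp(U[, L$sRf])
  out <- matrix(unlist(cols), nrow = n,
                dimnames = list(NULL, names(cols)))
  out
}

constrain_condition <- function(U, L, info) {
  n <- nrow(U)
  cols <- list()
  for (d in seq_along(info$others)) {
    cols[[paste0("condition.", info$others[d])]] <- U[, L$bOrd[d]]
  }
  cc <- t(apply(U[, L$thc, drop = FALSE], 1, function(th) {
    cumsum(c(th[1], exp(th[-1])))
  }))
  shift <- U[, L$bOrd, drop = FALSE] %*% info$x_bar
  for (m in 1:(L$K - 1)) cols[[paste0("cutpoint.", m)]] <- cc[, m] + shift
  for (t in seq_along(info$subjects)) {
    cols[[paste0("ranef_subject.", info$subjects[t])]] <- U[, L$rRs[t]]
  }
  for (t in seq_along(info$faces)) {
    cols[[paste0("ranef_face.", info$faces[t])]] <- U[, L$rRf[t]]
  }
  cols[["sigma_subject"]] <- exp(U[, L$sRs])
  cols[["sigma_face"]] <- exp(U[, L$sRf])
  matrix(unlist(cols), nrow = n, dimnames = list(NULL, names(cols)))
}

# parameter metadata for tidy()/significance tables, from column names
param_meta <- function(terms) {
  split <- strsplit(terms, ".", fixed = TRUE)
  tibble(
    term = terms,
    block = purrr::map_chr(split, 1),
    class = dplyr::case_when(
      grepl("^ranef", terms) ~ "ranef",
      grepl("^sigma", terms) ~ "scale",
      grepl("^phi", terms) ~ "precision",
      grepl("^cutpoint", terms) ~ "cutpoint",
      TRUE ~ "fixed"
    ),
    area = purrr::map_chr(split, function(s) {
      if (length(s) >= 2 && s[2] %in% .areas &&
          !s[1] %in% c("rating_gaze")) s[2] else NA_character_
    }),
    predictor = purrr::map_chr(split, function(s) {
      if (s[1] %in% c("bern_beta", "beta_beta")) s[3]
      else if (s[1] %in% c("rating_trait", "rating_gaze", "condition")) s[2]
      else NA_character_
    }),
    level = purrr::map_chr(split, function(s) {
      if (grepl("^ranef", s[1])) s[length(s)] else NA_character_
    })
  )
}

finish_fit <- function(res, draws_by_chain, info, config, model, data) {
  draws <- do.call(rbind, draws_by_chain)
  chain <- rep(seq_along(draws_by_chain),
               vapply(draws_by_chain, nrow, integer(1)))
  rh <- apply_rhat(draws, chain)
  fit <- structure(list(
    model = model,
    draws = draws, chain = chain, lp = unlist(res$lp),
    meta = param_meta(colnames(draws)),
    rhat = rh, config = config,
    accept_rate = res$accept, divergences = res$divergences,
    subjects = info$subjects, faces = info$faces,
    task = info$task %||% NA_character_,
    reference = info$reference %||% NA_character_,
    trait_means = info$p_bar, data = data
  ), class = "impress_fit")
  if (!convergence_ok(fit)) {
    warn(sprintf(
      "MCMC did not meet the convergence rule: max split R-hat = %.3f (>= 1.1)",
      max(rh, na.rm = TRUE)), class = "gazeimpress_convergence_warning")
  }
  fit
}

apply_rhat <- function(draws, chain) {
  if (length(unique(chain)) < 2L) {
    return(setNames(rep(NA_real_, ncol(draws)), colnames(draws)))
  }
  vapply(seq_len(ncol(draws)), function(p) {
    rhat(matrix_by_chain(draws[, p], chain))
  }, numeric(1)) %>% setNames(colnames(draws))
}

matrix_by_chain <- function(x, chain) {
  vapply(unique(chain), function(ch) x[chain == ch], numeric(sum(chain == chain[1])))
}

#' Convergence rule
#'
#' A fit is declared converged when the split R-hat of every parameter is
#' below 1.1.
#'
#' @param fit An [fit_joint()] or [fit_condition_model()] result.
#' @return Logical.
#' @export
convergence_ok <- function(fit) {
  all(is.na(fit$rhat)) || max(fit$rhat, na.rm = TRUE) < 1.1
}

#' Fit the joint gaze and rating model
#'
#' Estimates, in one posterior, the zero-inflated beta gaze model for the
#' three areas (Bernoulli looking probability and beta gaze weight, each a
#' logistic regression on the observer's five traits with subject and face
#' random intercepts) together with the ordered-logistic rating model
#' (three gaze main effects, three pairwise and one three-way interaction,
#' five trait effects, random intercepts). Sampling is Hamiltonian Monte
#' Carlo with analytic gradients, a dual-averaging step size and a
#' diagonal mass matrix adapted during warmup. Priors: Normal(0, sd 10) on
#' fixed effects and cutpoints (ordered), half-Normal(0, 10) on beta
#' precisions, Gamma(10, 10) on random-effect scales.
#'
#' @param data Study data: one row per subject x face with gaze weights
#'   (`g_eye`, `g_nose`, `g_mouth` in `[0, 1)`), `rating` in 1..7 and the
#'   five trait columns; see [sim_study()].
#' @param config An [mcmc_config()].
#' @param init_step Initial leapfrog step size (adapted during warmup).
#' @return An `impress_fit` object holding named posterior draws (raw
#'   covariate scale), per-parameter split R-hat, and the data needed for
#'   summaries and predictive curves. A warning is raised if any R-hat is
#'   at or above 1.1.
#' @export
#' @examples
#' \donttest{
#' study <- sim_study(n_subjects = 12, n_faces_per_task = 6, seed = 1)
#' fit <- fit_joint(study$data,
#'                  mcmc_config(chains = 2, iterations = 600, warmup = 300))
#' tidy(fit)
#' }
fit_joint <- function(data, config = mcmc_config(), init_step = 0.05) {
  stopifnot(inherits(config, "mcmc_config"))
  info <- joint_model_data(data)
  res <- run_chains(info$cpp, config, init_step)
  constrained <- lapply(res$draws, constrain_joint, L = res$layout, info = info)
  finish_fit(res, constrained, info, config, "joint", data)
}

#' Fit the between-condition rating model
#'
#' Ordered-logistic model of ratings on gaze-manipulation condition
#' (reference coding: the `Free` condition is fixed at 0) with subject and
#' face random intercepts, plus posterior draws of the pairwise contrasts
#' of each manipulated condition against the reference.
#'
#' @param data Tibble with `subject_id`, `stimulus_id`, `condition`,
#'   `rating`; at least two conditions.
#' @param reference Reference condition (default `"Free"`).
#' @inheritParams fit_joint
#' @return An `impress_fit` object; [condition_contrasts()] extracts the
#'   contrast summaries.
#' @export
fit_condition_model <- function(data, config = mcmc_config(),
                                reference = "Free", init_step = 0.05) {
  stopifnot(inherits(config, "mcmc_config"))
  info <- condition_model_data(data, reference)
  res <- run_chains(info$cpp, config, init_step)
  constrained <- lapply(res$draws, constrain_condition,
                        L = res$layout, info = info)
  finish_fit(res, constrained, info, config, "condition", data)
}

#' @export
print.impress_fit <- function(x, ...) {
  cat(sprintf("<impress_fit: %s model> %d chains x %d draws; %d parameters\n",
              x$model, length(unique(x$chain)),
              sum(x$chain == x$chain[1]), ncol(x$draws)))
  cat(sprintf("  max split R-hat %.3f (%s); mean acceptance %.2f; %d divergence(s)\n",
              max(x$rhat, na.rm = TRUE),
              if (convergence_ok(x)) "converged" else "NOT converged",
              mean(x$accept_rate), x$divergences))
  invisible(x)
}

#' Posterior draws of condition contrasts
#'
#' Contrast draws of each manipulated condition against the reference
#' (`Eye - Free`, `Nose - Free`, `Mouth - Free` under reference coding the
#' contrast equals the condition effect itself), with posterior means and
#' 95% HDIs.
#'
#' @param fit A [fit_condition_model()] result.
#' @param mass HDI mass.
#' @return A tibble with `contrast`, `mean`, `lower`, `upper`,
#'   `significant`.
#' @export
condition_contrasts <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "impress_fit"))
  if (fit$model != "condition") {
    stop_config("`fit` must come from fit_condition_model()")
  }
  terms <- grep("^condition\\.", colnames(fit$draws), value = TRUE)
  purrr::map_dfr(terms, function(tm) {
    d <- fit$draws[, tm]
    h <- hdi(d, mass)
    tibble(contrast = paste0(sub("^condition\\.", "", tm), "-", fit$reference),
           mean = mean(d), lower = h[1], upper = h[2],
           significant = h[1] > 0 | h[2] < 0)
  })
}
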