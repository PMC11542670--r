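#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat compares the within-half and
#' between-half variances and approaches 1 at convergence. Chains with
#' zero variance are defined to have R-hat 1, with a warning.
#'
#' @param draws An `iterations x chains` matrix of draws for one parameter
#'   (at least 2 chains, or 1 chain which is split into halves).
#' @return The split R-hat statistic.
#' @export
#' @examples
#' rhat(matrix(rnorm(2000), ncol = 2))  # ~ 1
rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) stop_data("need at least 4 draws per chain for split R-hat")
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(half), ch], draws[half + seq_len(half), ch])
  }))
  m <- ncol(splits); nn <- nrow(splits)
  W <- mean(apply(splits, 2, stats::var))
  if (W == 0) {
    warn("zero within-chain variance: split R-hat defined as 1")
    return(1)
  }
  B <- nn * stats::var(colMeans(splits))
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

#' Highest density interval
#'
#' Shortest contiguous interval containing a given mass of the draws
#' (assumes a unimodal posterior, as holds for the regression parameters
#' here). For a skewed sample this is narrower than the equal-tailed
#' interval.
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return Named vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e4))  # close to c(-1.96, 1.96)
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop_domain("`mass` must lie strictly in (0, 1)")
  }
  if (length(draws) < 2L) stop_data("need at least 2 draws")
  x <- sort(draws)
  n <- length(x)
  m <- min(n, ceiling(mass * n))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1L])
}

# traits are reported as AGR/CON/...; gaze and condition predictors as
# capitalized area names (Eye, Nose, Mouth, Eye:Nose, ...)
format_predictor <- function(x) {
  if (x %in% .traits) return(toupper(x))
  paste(vapply(strsplit(x, ":")[[1]], function(s) {
    paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  }, character(1)), collapse = ":")
}

#' Significance table of fixed effects
#'
#' Summarises the fixed effects of a fit in the layout of the reference
#' tables: model component, impression task, area (for the gaze models),
#' predictor, posterior mean and 95% HDI. An effect is significant when its
#' HDI excludes 0 (flag computed before rounding); by default only
#' significant rows are returned, mirroring how such tables are reported.
#'
#' @param fit An `impress_fit`.
#' @param mass HDI mass.
#' @param all Return all fixed effects (with a `significant` column)
#'   rather than only the significant ones.
#' @param digits Rounding applied to the reported mean and bounds.
#' @return A tibble with columns `model`, `impression`, `area`,
#'   `predictor`, `mean`, `lower`, `upper`, `significant`.
#' @export
significance_table <- function(fit, mass = 0.95, all = FALSE, digits = 3) {
  stopifnot(inherits(fit, "impress_fit"))
  meta <- fit$meta %>% filter(.data$class == "fixed",
                              !is.na(.data$predictor))
  rows <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    tm <- meta$term[i]
    d <- fit$draws[, tm]
    h <- hdi(d, mass)
    tibble(
      model = c(bern_beta = "Bernoulli", beta_beta = "Beta",
                rating_gaze = "Ordinal", rating_trait = "Ordinal",
                condition = "Ordinal")[[meta$block[i]]],
      impression = fit$task,
      area = meta$area[i],
      predictor = format_predictor(meta$predictor[i]),
      mean = round(mean(d), digits),
      lower = round(h[1], digits), upper = round(h[2], digits),
      significant = h[1] > 0 | h[2] < 0
    )
  })
  if (!all) rows <- filter(rows, .data$significant)
  rows
}

#' Proportions of significant random effects
#'
#' For each model component, the percentage of subject random intercepts,
#' face random intercepts, and of the pooled (subject or face) set whose
#' 95% HDI excludes 0.
#'
#' @param fit An `impress_fit`.
#' @param mass HDI mass.
#' @return A tibble with columns `model`, `impression`, `subject_pct`,
#'   `face_pct`, `either_pct`.
#' @export
ranef_significance_props <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "impress_fit"))
  sig <- function(terms) {
    vapply(terms, function(tm) {
      h <- hdi(fit$draws[, tm], mass)
      h[1] > 0 | h[2] < 0
    }, logical(1))
  }
  blocks <- if (fit$model == "joint") {
    list(Bernoulli = c("ranef_bern_subject", "ranef_bern_face"),
         Beta = c("ranef_beta_subject", "ranef_beta_face"),
         Ordinal = c("ranef_rating_subject", "ranef_rating_face"))
  } else {
    list(Ordinal = c("ranef_subject", "ranef_face"))
  }
  purrr::map_dfr(names(blocks), function(bl) {
    s_terms <- fit$meta$term[fit$meta$block == blocks[[bl]][1]]
    f_terms <- fit$meta$term[fit$meta$block == blocks[[bl]][2]]
    s_sig <- sig(s_terms); f_sig <- sig(f_terms)
    tibble(model = bl, impression = fit$task,
           subject_pct = 100 * mean(s_sig),
           face_pct = 100 * mean(f_sig),
           either_pct = 100 * (sum(s_sig) + sum(f_sig)) /
             (length(s_sig) + length(f_sig)))
  })
}
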