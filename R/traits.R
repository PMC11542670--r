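#' Simulate Big Five trait profiles
#'
#' Draws per-subject trait scores from a truncated normal on the 1-7 scale
#' of the Ten-Item Personality Inventory. Means and standard deviations can
#' be given per trait (recycled otherwise).
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param mean,sd Trait means and standard deviations before truncation;
#'   scalars or length-5 vectors in the order agr, con, ext, neu, ope.
#' @param seed Optional integer seed; identical seeds give identical
#'   profiles.
#' @return A tibble with columns `subject_id`, `agr`, `con`, `ext`, `neu`,
#'   `ope`; all scores lie in `[1, 7]`.
#' @export
#' @examples
#' sim_traits(3, seed = 1)
sim_traits <- function(n_subjects, mean = 4, sd = 1.2, seed = NULL) {
  if (!is_count(n_subjects)) stop_config("`n_subjects` must be a count >= 0")
  if (any(sd <= 0) || !length(mean) %in% c(1L, 5L) ||
      !length(sd) %in% c(1L, 5L)) {
    stop_config("`mean` and `sd` must be scalars or length-5, with sd > 0")
  }
  mean <- rep_len(mean, 5L); sd <- rep_len(sd, 5L)
  with_seed(seed, {
    out <- tibble(subject_id = sprintf("S%03d", seq_len(n_subjects)))
    out[.traits] <- lapply(seq_len(5L), function(l) {
      rtruncnorm(n_subjects, mean[l], sd[l], 1, 7)
    })
    out
  })
}
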