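#' Model parameter sets
#'
#' `impress_params()` builds and validates the full parameter set of the
#' joint model for one impression task: the zero-inflated beta gaze model
#' (per-area intercepts, five trait coefficients for the Bernoulli and beta
#' components, precisions, random-effect scales), the ordered-logistic rating
#' model (seven gaze terms, five trait coefficients, six cutpoints for the
#' 7-point scale, random-effect scales), and optionally the
#' between-condition rating model (`Eye`/`Nose`/`Mouth` effects with `Free`
#' as the zero reference). Areas are ordered eye, nose, mouth and traits
#' agr, con, ext, neu, ope throughout.
#'
#' `default_true_params()` returns the ground-truth parameter set used by
#' the synthetic-study generator. Its non-zero effects mirror the kind of
#' structure the model is built to detect: extraversion raises the
#' probability of looking at the eyes (+0.8 on the logit scale),
#' agreeableness lowers the gaze weight on the nose (-0.3), agreeableness
#' raises impression ratings (+0.4), and looking at the eyes raises ratings
#' in the condition model (+0.5).
#'
#' @param zib List with `alpha_bern`, `beta_bern` (3 x 5), `alpha_beta`,
#'   `beta_beta` (3 x 5), `phi` (length 3, > 0) and `sigma` (list of four
#'   length-3 positive vectors: `bern_subject`, `bern_face`, `beta_subject`,
#'   `beta_face`).
#' @param rating List with `beta_gaze` (length 7), `beta_trait` (length 5),
#'   `cutpoints` (length 6, strictly increasing) and `sigma` (list with
#'   positive `subject`, `face`).
#' @param condition Optional list with `beta` (named `Eye`, `Nose`,
#'   `Mouth`), `cutpoints` and `sigma` as above.
#' @return An object of class `impress_params`.
#' @export
#' @examples
#' params <- default_true_params()
#' params$zib$beta_bern["eye", "ext"]
impress_params <- function(zib, rating, condition = NULL) {
  dimnames(zib$beta_bern) <- dimnames(zib$beta_beta) <- list(.areas, .traits)
  names(zib$alpha_bern) <- names(zib$alpha_beta) <- names(zib$phi) <- .areas
  names(rating$beta_gaze) <- c(.areas, "eye:nose", "eye:mouth", "nose:mouth",
                               "eye:nose:mouth")
  names(rating$beta_trait) <- .traits
  x <- structure(list(zib = zib, rating = rating, condition = condition),
                 class = "impress_params")
  validate_params(x)
}

validate_params <- function(x) {
  z <- x$zib; r <- x$rating
  stopifnot(
    length(z$alpha_bern) == 3L, length(z$alpha_beta) == 3L,
    identical(dim(z$beta_bern), c(3L, 5L)),
    identical(dim(z$beta_beta), c(3L, 5L)),
    length(r$beta_gaze) == 7L, length(r$beta_trait) == 5L,
    length(r$cutpoints) == 6L
  )
  if (any(z$phi <= 0)) stop_config("beta precisions `phi` must be > 0")
  if (any(diff(r$cutpoints) <= 0)) {
    stop_config("rating cutpoints must be strictly increasing")
  }
  if (any(unlist(z$sigma) <= 0) || any(unlist(r$sigma) <= 0)) {
    stop_config("random-effect scales must be > 0")
  }
  if (!is.null(x$condition)) {
    cn <- x$condition
    if (!all(c("Eye", "Nose", "Mouth") %in% names(cn$beta))) {
      stop_config("condition effects must be named Eye, Nose, Mouth")
    }
    if (any(diff(cn$cutpoints) <= 0)) {
      stop_config("condition-model cutpoints must be strictly increasing")
    }
    if (any(unlist(cn$sigma) <= 0)) {
      stop_config("condition-model random-effect scales must be > 0")
    }
  }
  x
}

#' @rdname impress_params
#' @export
default_true_params <- function() {
  beta_bern <- matrix(0, 3, 5)
  beta_bern[1, 3] <- 0.8          # extraversion -> looking at the eyes
  beta_beta <- matrix(0, 3, 5)
  beta_beta[2, 1] <- -0.3         # agreeableness -> gaze weight on the nose
  zib <- list(
    # intercepts chosen so that, at the trait-scale midpoint 4, the looking
    # probabilities are roughly 0.75/0.75/0.60 and the mean non-zero gaze
    # weights roughly 0.35/0.40/0.25 (eye/nose/mouth)
    alpha_bern = c(1.1 - 0.8 * 4, 1.1, 0.4),
    beta_bern  = beta_bern,
    alpha_beta = c(-0.62, -0.41 + 0.3 * 4, -1.10),
    beta_beta  = beta_beta,
    phi        = c(8, 8, 8),
    sigma = list(bern_subject = rep(0.5, 3), bern_face = rep(0.3, 3),
                 beta_subject = rep(0.3, 3), beta_face = rep(0.2, 3))
  )
  rating <- list(
    beta_gaze  = c(0.5, -0.5, 0.3, 0, 0, 0, 0),
    beta_trait = c(0.4, 0, 0, 0, 0),   # agreeableness -> higher ratings
    # centered near the typical linear predictor (~1.7 at trait midpoint)
    cutpoints  = 1.7 + c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
    sigma      = list(subject = 0.3, face = 0.5)
  )
  condition <- list(
    beta      = c(Eye = 0.5, Nose = 0, Mouth = 0),
    cutpoints = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
    sigma     = list(subject = 0.3, face = 0.5)
  )
  impress_params(zib, rating, condition)
}

#' @rdname impress_params
#' @export
null_true_params <- function() {
  x <- default_true_params()
  x$zib$alpha_bern[] <- 0
  x$zib$alpha_beta[] <- 0
  x$zib$beta_bern[] <- 0
  x$zib$beta_beta[] <- 0
  x$rating$beta_gaze[] <- 0
  x$rating$beta_trait[] <- 0
  x$rating$cutpoints <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  x$condition$beta[] <- 0
  validate_params(x)
}

#' Read and write parameter sets as JSON
#'
#' Serializes an [impress_params] object with named, indexed coefficients
#' (trait order agr, con, ext, neu, ope; area order eye, nose, mouth).
#'
#' @param params An [impress_params] object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns an [impress_params] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "impress_params"))
  out <- unclass(params)
  if (!is.null(out$condition)) {
    out$condition$beta <- as.list(out$condition$beta)  # keep the names
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) {
    if (is.matrix(m)) m else matrix(unlist(m), 3, 5, byrow = TRUE)
  }
  raw$zib$beta_bern <- as_mat(raw$zib$beta_bern)
  raw$zib$beta_beta <- as_mat(raw$zib$beta_beta)
  if (!is.null(raw$condition)) {
    raw$condition$beta <- unlist(raw$condition$beta)
  }
  impress_params(raw$zib, raw$rating, raw$condition)
}
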