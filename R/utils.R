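# internal helpers: validation, truncated normal draws, seed handling

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_data <- function(msg) abort(msg, class = "gazeimpress_data_error")
stop_config <- function(msg) abort(msg, class = "gazeimpress_config_error")
stop_domain <- function(msg) abort(msg, class = "gazeimpress_domain_error")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop_config(sprintf("`%s` must be a single number in [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

# with_seed: run code under a seed without clobbering the caller's RNG state;
# a NULL seed uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a child seed below 2^31 from a top-level seed and a stream label
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.double(seed) * 7919 + h * 104729) %% 2147483629 + 1
}

# inverse-CDF truncated normal draw on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}
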