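# Internal helpers shared across modules.

#' Derive a deterministic sub-seed from a master seed and a stream name
#'
#' Named substreams decouple the random sources of the pipeline (phantom
#' geometry, photon detection, electronic noise, ...) so that toggling one
#' noise source does not perturb the draws of another.
#'
#' @param seed Master integer seed.
#' @param name Character label of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# scalar checks ---------------------------------------------------------------

assert_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Gaussian FWHM <-> sigma (2 * sqrt(2 * log(2)) = 2.3548...)
FWHM_OVER_SIGMA <- 2 * sqrt(2 * log(2))

fwhm_to_sigma <- function(fwhm) fwhm / FWHM_OVER_SIGMA
sigma_to_fwhm <- function(sigma) sigma * FWHM_OVER_SIGMA

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
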