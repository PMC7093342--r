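#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so that seeded generators never disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with a stream index (e.g. participant number) and a
#' salt distinguishing the purpose of the stream (design, observer, ...).
#' Kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param index Non-negative stream index.
#' @param salt Small integer separating independent uses of the same index.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, index = 0L, salt = 0L) {
  s <- (abs(as.numeric(seed)) + 7919 * (as.numeric(index) + 1) +
          104729 * (as.numeric(salt) + 1)) %% 2147483587
  as.integer(s)
}

# round half away from zero (keypad responses have no banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Discretize a continuous report onto the integer response scale
#'
#' Rounds half away from zero, then clips to the scale bounds.
#'
#' @param x Numeric vector of continuous reports.
#' @param scale Length-2 numeric, response scale bounds (default 1-9).
#' @return Numeric vector of integers within `scale`.
#' @export
discretize_rating <- function(x, scale = c(1, 9)) {
  pmin(scale[2], pmax(scale[1], round_half_away(x)))
}

# small FNV-1a hash over a character scalar, for config provenance
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_with <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
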