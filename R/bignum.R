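#' @useDynLib gaitshield, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Big integers are plain R character strings holding (possibly signed) hex,
# as produced by OpenSSL. These helpers keep the rest of the package free of
# base-conversion noise.

bn_zero <- "0"
bn_one  <- "1"

bn_from_int <- function(x) {
  stopifnot(is.numeric(x), all(abs(x) < 2^53))
  vapply(x, function(v) .bn_from_dec(format(v, scientific = FALSE)), "")
}

bn_to_num <- function(hex) {
  as.numeric(vapply(hex, .bn_to_dec, "", USE.NAMES = FALSE))
}

bn_eq <- function(a, b) .bn_cmp(a, b) == 0L
bn_lt <- function(a, b) .bn_cmp(a, b) < 0L

#' Draw raw entropy bytes
#'
#' Two entropy channels are used in the package: a cryptographic channel
#' (OS entropy via OpenSSL) for production keys and encryption randomizers,
#' and R's seedable RNG for reproducible test keys and everything
#' statistical. `seeded = TRUE` draws from the current R RNG stream.
#'
#' @param n number of bytes.
#' @param seeded if `TRUE`, derive the bytes from R's RNG (reproducible under
#'   `set.seed`); otherwise use OS cryptographic entropy.
#' @return a raw vector of length `n`.
#' @keywords internal
rand_bytes <- function(n, seeded = FALSE) {
  if (seeded) {
    as.raw(sample.int(256L, n, replace = TRUE) - 1L)
  } else {
    .crypto_rand_bytes(as.integer(n))
  }
}

# Uniform big integer in [1, bound) drawn by rejection from entropy bytes.
bn_random_below <- function(bound_hex, seeded = FALSE, max_tries = 10000L) {
  bits <- .bn_bits(bound_hex)
  nbytes <- as.integer(ceiling(bits / 8)) + 1L
  for (i in seq_len(max_tries)) {
    cand <- .bn_mod(.bn_from_bytes(rand_bytes(nbytes, seeded)), bound_hex)
    if (.bn_cmp(cand, bn_zero) > 0L) return(cand)
  }
  stop("failed to draw a random residue")
}

# Run code with a locally seeded, pinned RNG (Mersenne-Twister + inversion),
# restoring the caller's RNG state afterwards. All deterministic randomness
# in the package flows through this.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
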