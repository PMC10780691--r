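#' Paillier cryptosystem with signed fixed-point encoding
#'
#' The Paillier scheme is an asymmetric, additively homomorphic cryptosystem
#' over \eqn{Z_{n^2}}: products of ciphertexts decrypt to sums of plaintexts,
#' and a ciphertext raised to an integer power decrypts to the plaintext
#' scaled by that integer. Those two primitives are exactly what is needed to
#' run a linear random projection on encrypted gait features.
#'
#' Keys are built from two random primes \eqn{p \ne q} of equal bit length:
#' \eqn{n = pq}, \eqn{g = n + 1},
#' \eqn{\lambda = (p-1)(q-1)} and \eqn{\mu = \lambda^{-1} \bmod n}.
#' With \eqn{g = n+1} decryption reduces to
#' \eqn{m = L(c^\lambda \bmod n^2)\,\mu \bmod n} with \eqn{L(x) = (x-1)/n}.
#'
#' Real-valued features are carried as signed fixed-point integers: a value
#' \eqn{x} at scale \eqn{s} is the mantissa \eqn{round(x \cdot 10^s) \bmod n},
#' with residues above \eqn{n/2} read back as negative (half-range signed
#' convention).
#'
#' @name paillier
NULL

MAX_PRIME_TRIES <- 100000L

prime_from_entropy <- function(bits, seeded) {
  nbytes <- as.integer(ceiling(bits / 8))
  for (i in seq_len(MAX_PRIME_TRIES)) {
    cand <- .bn_candidate_from_bytes(rand_bytes(nbytes, seeded), as.integer(bits))
    if (.bn_is_prime(cand)) return(cand)
  }
  stop("key-generation error: no prime found within the attempt bound")
}

new_pubkey <- function(n, prime_bits) {
  n_sq <- .bn_mul(n, n)
  structure(
    list(n = n, g = .bn_add(n, bn_one), n_sq = n_sq,
         prime_bits = as.integer(prime_bits),
         key_id = substr(.sha256_hex(n), 1L, 16L)),
    class = "paillier_pubkey")
}

new_privkey <- function(lam, mu, n) {
  structure(
    list(lam = lam, mu = mu, n = n,
         key_id = substr(.sha256_hex(n), 1L, 16L)),
    class = "paillier_privkey")
}

#' Generate a Paillier keypair
#'
#' Draws two distinct Miller-Rabin-certified primes of exactly `prime_bits`
#' bits (top bit forced) and regenerates until the modulus has exactly
#' `2 * prime_bits` bits, so the advertised key size always holds.
#'
#' @param prime_bits bits per prime (>= 8). The modulus `n` has
#'   `2 * prime_bits` bits; the headline configuration uses 64-bit primes,
#'   i.e. a 128-bit modulus.
#' @param crypto_seed optional integer. When supplied, prime entropy is drawn
#'   from R's seeded RNG so that test keys are reproducible; when `NULL`
#'   (production), OS cryptographic entropy is used.
#' @return a list with elements `public` (class `paillier_pubkey`) and
#'   `private` (class `paillier_privkey`).
#' @examples
#' kp <- generate_keypair(16, crypto_seed = 1)
#' kp$public$prime_bits
#' @export
generate_keypair <- function(prime_bits, crypto_seed = NULL) {
  stopifnot(prime_bits >= 8)
  gen <- function() {
    seeded <- !is.null(crypto_seed)
    for (i in seq_len(1000L)) {
      p <- prime_from_entropy(prime_bits, seeded)
      q <- prime_from_entropy(prime_bits, seeded)
      if (bn_eq(p, q)) next
      n <- .bn_mul(p, q)
      if (.bn_bits(n) != 2L * prime_bits) next
      return(keypair_from_primes(p, q, prime_bits = prime_bits))
    }
    stop("key-generation error: modulus size not reached within attempt bound")
  }
  if (is.null(crypto_seed)) gen() else with_local_seed(crypto_seed, gen())
}

#' Build a keypair from explicit primes
#'
#' Intended for worked examples and tests with tiny, known primes (the
#' smallest interesting modulus is `p = 5`, `q = 7`, `n = 35`). Production
#' keys should come from [generate_keypair()].
#'
#' @param p,q distinct primes, as numbers or hex strings.
#' @param prime_bits recorded prime size; defaults to the actual bit length
#'   of `p`.
#' @return as [generate_keypair()].
#' @export
keypair_from_primes <- function(p, q, prime_bits = NULL) {
  if (is.numeric(p)) p <- bn_from_int(p)
  if (is.numeric(q)) q <- bn_from_int(q)
  if (bn_eq(p, q)) stop("p and q must be distinct")
  n <- .bn_mul(p, q)
  lam <- .bn_mul(.bn_sub(p, bn_one), .bn_sub(q, bn_one))
  mu <- .bn_mod_inverse(lam, n)
  if (is.null(prime_bits)) prime_bits <- .bn_bits(p)
  list(public = new_pubkey(n, prime_bits), private = new_privkey(lam, mu, n))
}

#' @export
print.paillier_pubkey <- function(x, ...) {
  cat(sprintf("Paillier public key: |n| = %d bits, key_id = %s\n",
              .bn_bits(x$n), x$key_id))
  invisible(x)
}

#' @export
print.paillier_privkey <- function(x, ...) {
  cat(sprintf("Paillier private key (lambda, mu): key_id = %s\n", x$key_id))
  invisible(x)
}

# ---- fixed-point encoding ---------------------------------------------------

new_encoded <- function(mantissa_hex, scale_exp) {
  structure(list(mantissa = mantissa_hex, scale_exp = as.integer(scale_exp)),
            class = "paillier_encoded")
}

#' Encode real values as signed fixed-point residues
#'
#' `value * 10^scale_exp` is rounded to the nearest integer and reduced mod
#' `n`; magnitudes of at least `n/2` are rejected because they would collide
#' with the negative half-range.
#'
#' @param value numeric vector to encode.
#' @param scale_exp non-negative decimal scale exponent (resolution
#'   `10^-scale_exp`). The package default for features and matrix entries
#'   is 6.
#' @param n modulus (hex string from a `paillier_pubkey`, or a number).
#' @return an object of class `paillier_encoded` holding mantissa residues
#'   and the scale.
#' @seealso [decode_real()]
#' @export
encode_real <- function(value, scale_exp, n) {
  stopifnot(is.numeric(value), scale_exp >= 0)
  if (is.numeric(n)) n <- bn_from_int(n)
  scaled <- round(value * 10^scale_exp)
  if (any(!is.finite(scaled))) stop("non-finite value cannot be encoded")
  if (any(abs(scaled) >= 2^53)) {
    stop("overflow error: mantissa exceeds exact double-integer range")
  }
  half <- .bn_div(.bn_sub(n, bn_one), "2")  # (n-1)/2
  mant <- vapply(scaled, function(m) {
    mh <- bn_from_int(m)
    abs_mh <- if (m < 0) .bn_sub(bn_zero, mh) else mh
    if (.bn_cmp(abs_mh, half) > 0L) {
      stop("overflow error: |value|*10^scale_exp >= n/2 breaks the signed convention")
    }
    .bn_mod(mh, n)
  }, "")
  new_encoded(mant, scale_exp)
}

#' Decode fixed-point residues back to reals
#'
#' Inverts [encode_real()]: residues above `n/2` are interpreted as negative
#' (half-range signed convention), then divided by `10^scale_exp`.
#'
#' @param enc a `paillier_encoded` object.
#' @param n modulus used at encoding time.
#' @return numeric vector.
#' @export
decode_real <- function(enc, n) {
  stopifnot(inherits(enc, "paillier_encoded"))
  if (is.numeric(n)) n <- bn_from_int(n)
  bn_to_num(decode_signed_hex(enc$mantissa, n)) / 10^enc$scale_exp
}

# Residue -> signed big integer (hex, possibly negative), half-range rule.
decode_signed_hex <- function(mantissa_hex, n) {
  half <- .bn_div(.bn_sub(n, bn_one), "2")
  vapply(mantissa_hex, function(m) {
    if (.bn_cmp(m, half) > 0L) .bn_sub(m, n) else m
  }, "", USE.NAMES = FALSE)
}

# ---- encryption -------------------------------------------------------------

new_ctvec <- function(values_hex, scale_exp, key_id) {
  structure(list(values = values_hex, scale_exp = as.integer(scale_exp),
                 key_id = key_id),
            class = "paillier_ctvec")
}

#' @export
length.paillier_ctvec <- function(x) length(x$values)

#' @export
print.paillier_ctvec <- function(x, ...) {
  cat(sprintf("Paillier ciphertext vector: %d elements, scale 10^-%d, key %s\n",
              length(x$values), x$scale_exp, x$key_id))
  invisible(x)
}

#' Encrypt encoded values
#'
#' Computes \eqn{c = g^m r^n \bmod n^2} for each mantissa, with an
#' independent randomizer \eqn{r} per element drawn coprime to `n`.
#' Encryption is therefore randomized: re-encrypting the same plaintext
#' yields a different ciphertext (semantic security).
#'
#' @param pub a `paillier_pubkey`.
#' @param m a `paillier_encoded` object (see [encode_real()]).
#' @param r optional explicit randomizer(s) in `(0, n)` coprime to `n`
#'   (number or hex, recycled); when `NULL`, randomizers come from the
#'   cryptographic RNG, or from R's RNG inside seeded blocks if
#'   `seeded_r = TRUE`.
#' @param seeded_r draw randomizers from R's seedable RNG (reproducible runs).
#' @return a `paillier_ctvec`.
#' @export
paillier_encrypt <- function(pub, m, r = NULL, seeded_r = FALSE) {
  stopifnot(inherits(pub, "paillier_pubkey"), inherits(m, "paillier_encoded"))
  len <- length(m$mantissa)
  if (is.null(r)) {
    r <- vapply(seq_len(len), function(i) {
      for (t in seq_len(100L)) {
        cand <- bn_random_below(pub$n, seeded = seeded_r)
        if (bn_eq(.bn_gcd(cand, pub$n), bn_one)) return(cand)
      }
      stop("failed to draw randomizer coprime to n")
    }, "")
  } else {
    if (is.numeric(r)) r <- bn_from_int(r)
    r <- rep_len(r, len)
    for (ri in r) {
      if (.bn_cmp(ri, bn_zero) <= 0L || .bn_cmp(ri, pub$n) >= 0L ||
          !bn_eq(.bn_gcd(ri, pub$n), bn_one)) {
        stop("invalid-randomizer error: r must lie in (0, n) with gcd(r, n) = 1")
      }
    }
  }
  new_ctvec(.paillier_encrypt_vec(pub$n, pub$n_sq, m$mantissa, r),
            m$scale_exp, pub$key_id)
}

#' Decrypt a ciphertext vector
#'
#' Applies \eqn{m = L(c^\lambda \bmod n^2)\,\mu \bmod n},
#' \eqn{L(x) = (x-1)/n}, preserving the fixed-point scale.
#'
#' @param priv a `paillier_privkey` matching the encrypting public key.
#' @param ct a `paillier_ctvec`.
#' @return a `paillier_encoded` object.
#' @export
paillier_decrypt <- function(priv, ct) {
  stopifnot(inherits(priv, "paillier_privkey"), inherits(ct, "paillier_ctvec"))
  if (!identical(priv$key_id, ct$key_id)) {
    stop("wrong-key error: ciphertext was produced under a different key")
  }
  n_sq <- .bn_mul(priv$n, priv$n)
  new_encoded(.paillier_decrypt_vec(priv$n, n_sq, priv$lam, priv$mu, ct$values),
              ct$scale_exp)
}

#' Homomorphic addition of ciphertexts
#'
#' The elementwise product of two ciphertext vectors modulo \eqn{n^2}
#' decrypts to the elementwise sum of the plaintexts. Both operands must
#' share the key and the fixed-point scale.
#'
#' @param c1,c2 `paillier_ctvec` objects of equal length.
#' @param pub the shared `paillier_pubkey`.
#' @return a `paillier_ctvec`.
#' @export
add_encrypted <- function(c1, c2, pub) {
  stopifnot(inherits(c1, "paillier_ctvec"), inherits(c2, "paillier_ctvec"))
  if (!identical(c1$key_id, c2$key_id)) stop("key error: mismatched keys")
  if (!identical(c1$key_id, pub$key_id)) stop("key error: wrong public key")
  if (c1$scale_exp != c2$scale_exp) {
    stop("scale error: operands carry different fixed-point scales")
  }
  if (length(c1$values) != length(c2$values)) stop("length mismatch")
  vals <- vapply(seq_along(c1$values), function(i) {
    .bn_mod_mul(c1$values[i], c2$values[i], pub$n_sq)
  }, "")
  new_ctvec(vals, c1$scale_exp, c1$key_id)
}

#' Homomorphic plaintext-scalar multiplication
#'
#' Raising a ciphertext to an encoded plaintext mantissa modulo \eqn{n^2}
#' decrypts to the product of plaintexts; the result's fixed-point scale is
#' the sum of the two scales.
#'
#' @param ct a `paillier_ctvec`.
#' @param k a `paillier_encoded` scalar (length 1, or one per element).
#' @param pub the `paillier_pubkey`.
#' @return a `paillier_ctvec` with `scale_exp = ct$scale_exp + k$scale_exp`.
#' @export
scalar_multiply <- function(ct, k, pub) {
  stopifnot(inherits(ct, "paillier_ctvec"), inherits(k, "paillier_encoded"))
  if (!identical(ct$key_id, pub$key_id)) stop("key error: wrong public key")
  km <- rep_len(k$mantissa, length(ct$values))
  vals <- vapply(seq_along(ct$values), function(i) {
    .bn_mod_exp(ct$values[i], km[i], pub$n_sq)
  }, "")
  new_ctvec(vals, ct$scale_exp + k$scale_exp, ct$key_id)
}

# ---- key / ciphertext serialization ----------------------------------------

#' Read and write Paillier keys and ciphertexts as JSON
#'
#' Keys are stored with hex-encoded big integers; the private-key file is for
#' the client role only and should be kept with restrictive permissions.
#' Ciphertext vectors are stored as arrays of hex values with their scale and
#' the key id.
#'
#' @param key,ct object to write.
#' @param path file path.
#' @return `read_*` return the reconstructed object; `write_*` return `path`
#'   invisibly.
#' @name paillier-io
NULL

#' @rdname paillier-io
#' @export
write_pubkey <- function(key, path) {
  stopifnot(inherits(key, "paillier_pubkey"))
  jsonlite::write_json(
    list(type = "paillier_public", n = key$n, g = key$g,
         prime_bits = key$prime_bits, key_id = key$key_id),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname paillier-io
#' @export
write_privkey <- function(key, path) {
  stopifnot(inherits(key, "paillier_privkey"))
  jsonlite::write_json(
    list(type = "paillier_private", lam = key$lam, mu = key$mu, n = key$n,
         key_id = key$key_id),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname paillier-io
#' @export
read_pubkey <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "paillier_public")) {
    stop("not a public key file: ", path)
  }
  new_pubkey(obj$n, obj$prime_bits)
}

#' @rdname paillier-io
#' @export
read_privkey <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "paillier_private")) {
    stop("not a private key file: ", path)
  }
  new_privkey(obj$lam, obj$mu, obj$n)
}

#' @rdname paillier-io
#' @export
write_ctvec <- function(ct, path) {
  stopifnot(inherits(ct, "paillier_ctvec"))
  jsonlite::write_json(
    list(type = "paillier_ctvec", scale_exp = ct$scale_exp,
         key_id = ct$key_id, values = ct$values),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname paillier-io
#' @export
read_ctvec <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "paillier_ctvec")) {
    stop("not a ciphertext file: ", path)
  }
  new_ctvec(unlist(obj$values), obj$scale_exp, obj$key_id)
}
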