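#' Cancelable-biometric Gaussian random projection
#'
#' A seeded Gaussian matrix \eqn{M} of size \eqn{j \times q} with
#' \eqn{q < j}, entries i.i.d. \eqn{N(0, 1/q)} (variance `1/n_components`),
#' maps a length-\eqn{j} gait feature vector \eqn{x} to a transformed
#' template \eqn{y = x M} of length \eqn{q}. Because the linear system
#' \eqn{M^T x = y} has more unknowns than equations, the transform is
#' noninvertible (Rouché–Capelli: infinitely many preimages), and because
#' the matrix is reproducible from a seed, a compromised template can be
#' revoked and reissued by rotating the seed (renewability). The same
#' projection can be run in the Paillier ciphertext domain, so the server
#' performing it never sees plaintext features.
#'
#' @name random-projection
NULL

#' Generate a seeded Gaussian projection matrix
#'
#' Entries are i.i.d. `N(0, 1/q)`, drawn from a pinned generator
#' (Mersenne-Twister with inversion sampling) so that a seed reproduces the
#' matrix bit-for-bit across platforms. The same matrix is used for every
#' subject; the seed is the cancelable-biometric secret.
#'
#' @param j original feature length (rows).
#' @param q transformed length (columns); for protection use `q < j`
#'   (default elsewhere in the package is `q = j - 1`).
#' @param seed integer matrix seed.
#' @return an object of class `projection_matrix` with fields `entries`
#'   (`j x q` numeric matrix), `j`, `q`, `seed`.
#' @export
rp_generate <- function(j, q, seed) {
  stopifnot(j >= 1, q >= 1)
  entries <- with_local_seed(seed, {
    matrix(stats::rnorm(j * q, mean = 0, sd = sqrt(1 / q)), nrow = j, ncol = q)
  })
  structure(list(entries = entries, j = as.integer(j), q = as.integer(q),
                 seed = as.integer(seed)),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("Gaussian projection matrix: %d x %d, seed %d\n", x$j, x$q, x$seed))
  invisible(x)
}

new_transformed <- function(values, seed, total_scale = 0L) {
  structure(list(values = as.numeric(values), seed = as.integer(seed),
                 total_scale = as.integer(total_scale)),
            class = "transformed_vector")
}

#' Project a plaintext feature vector
#'
#' @param x numeric vector of length `M$j`.
#' @param M a `projection_matrix`.
#' @return a `transformed_vector` with `values = as.numeric(x %*% M$entries)`.
#' @export
rp_project <- function(x, M) {
  stopifnot(inherits(M, "projection_matrix"))
  if (length(x) != M$j) {
    stop(sprintf("length mismatch: x has %d elements, matrix expects %d",
                 length(x), M$j))
  }
  new_transformed(as.numeric(x %*% M$entries), M$seed)
}

#' Quantize a projection matrix to integer mantissas
#'
#' Ciphertext exponentiation needs integer exponents, so matrix entries are
#' rounded to `round(entries * 10^scale_exp)` before entering the encrypted
#' domain; the per-entry dequantization error is at most
#' `0.5 * 10^-scale_exp`.
#'
#' @param M a `projection_matrix`.
#' @param scale_exp non-negative decimal scale (default 6).
#' @return class `quantized_projection_matrix`: integer `mantissas`
#'   (stored as numeric), `scale_exp`, `j`, `q`, `seed`.
#' @export
rp_quantize <- function(M, scale_exp = 6L) {
  stopifnot(inherits(M, "projection_matrix"), scale_exp >= 0)
  structure(list(mantissas = round(M$entries * 10^scale_exp),
                 scale_exp = as.integer(scale_exp),
                 j = M$j, q = M$q, seed = M$seed),
            class = "quantized_projection_matrix")
}

#' Dequantize back to a real matrix
#' @param Mq a `quantized_projection_matrix`.
#' @return numeric matrix.
#' @export
rp_dequantize <- function(Mq) {
  stopifnot(inherits(Mq, "quantized_projection_matrix"))
  Mq$mantissas / 10^Mq$scale_exp
}

#' Signed-overflow guard for the encrypted inner product
#'
#' The encrypted projection accumulates \eqn{j} products of fixed-point
#' mantissas inside the half-range signed convention of the modulus. This
#' guard checks, in exact big-integer arithmetic, that the worst-case
#' accumulated magnitude
#' `j * max_abs_feature * 10^feat_scale * max_abs_entry * 10^mat_scale`
#' stays strictly below `(n - 1) / 2`; an encrypted run must refuse to start
#' otherwise, since a wrapped sum would decrypt to garbage.
#'
#' @param pub a `paillier_pubkey`.
#' @param j feature length.
#' @param feat_scale,mat_scale decimal scale exponents of features / matrix.
#' @param max_abs_feature,max_abs_entry magnitude bounds on the inputs.
#' @return `TRUE` iff the bound holds.
#' @export
overflow_bound_ok <- function(pub, j, feat_scale, mat_scale,
                              max_abs_feature, max_abs_entry) {
  stopifnot(j > 0, feat_scale > 0 || feat_scale == 0, max_abs_feature > 0,
            max_abs_entry > 0)
  f_m <- bn_from_int(ceiling(max_abs_feature * 10^feat_scale))
  e_m <- bn_from_int(ceiling(max_abs_entry * 10^mat_scale))
  prod <- .bn_mul(.bn_mul(bn_from_int(j), f_m), e_m)
  half <- .bn_div(.bn_sub(pub$n, bn_one), "2")  # (n-1)/2
  bn_lt(prod, half)
}

#' Run the random projection in the ciphertext domain
#'
#' Computes, for each output component \eqn{k},
#' \eqn{y_k = \prod_i c_i^{\,m_{ik}} \bmod n^2}
#' where \eqn{c_i} are the encrypted feature mantissas and \eqn{m_{ik}} the
#' quantized matrix mantissas (negatives reduced mod \eqn{n}). By the
#' Paillier homomorphism this decrypts to the exact integer matrix–vector
#' product of the mantissas. The server that executes this sees only
#' ciphertexts.
#'
#' @param enc_x a `paillier_ctvec` of length `Mq$j` (one scale throughout).
#' @param Mq a `quantized_projection_matrix`.
#' @param pub the `paillier_pubkey`.
#' @param max_abs_feature magnitude bound on the plaintext features, used by
#'   the overflow guard (default 10^3 image-pixel-scale features).
#' @return a `paillier_ctvec` of length `Mq$q` with
#'   `scale_exp = enc_x$scale_exp + Mq$scale_exp`.
#' @export
rp_project_encrypted <- function(enc_x, Mq, pub, max_abs_feature = 1e3) {
  stopifnot(inherits(enc_x, "paillier_ctvec"),
            inherits(Mq, "quantized_projection_matrix"))
  if (!identical(enc_x$key_id, pub$key_id)) stop("key error: wrong public key")
  if (length(enc_x$values) != Mq$j) {
    stop(sprintf("length mismatch: %d ciphertexts for a %d-row matrix",
                 length(enc_x$values), Mq$j))
  }
  max_entry <- max(abs(Mq$mantissas)) / 10^Mq$scale_exp
  if (!overflow_bound_ok(pub, Mq$j, enc_x$scale_exp, Mq$scale_exp,
                         max_abs_feature, max(max_entry, 1e-12))) {
    stop("overflow error: modulus too small for this j / scale configuration")
  }
  exp_hex <- matrix(
    vapply(as.vector(Mq$mantissas),
           function(m) .bn_mod(bn_from_int(m), pub$n), ""),
    nrow = Mq$j, ncol = Mq$q)
  vals <- .paillier_project_vec(pub$n_sq, enc_x$values, exp_hex)
  new_ctvec(vals, enc_x$scale_exp + Mq$scale_exp, enc_x$key_id)
}

#' Decrypt an encrypted transformed vector
#'
#' Componentwise Paillier decryption followed by signed half-range decoding
#' and division by `10^total_scale`. Crucially, the result does not depend
#' on which keypair carried the computation: for the same features and
#' matrix, decryption under different hospitals' keys yields the identical
#' transformed template.
#'
#' @param priv a `paillier_privkey`.
#' @param enc_y a `paillier_ctvec` as returned by [rp_project_encrypted()].
#' @param total_scale total decimal scale; defaults to `enc_y$scale_exp`.
#' @param seed matrix seed to record on the output (provenance only).
#' @return a `transformed_vector`.
#' @export
rp_decrypt_transformed <- function(priv, enc_y, total_scale = NULL, seed = NA_integer_) {
  stopifnot(inherits(priv, "paillier_privkey"))
  if (is.null(total_scale)) total_scale <- enc_y$scale_exp
  dec <- paillier_decrypt(priv, enc_y)
  n <- priv$n
  vals <- bn_to_num(decode_signed_hex(dec$mantissa, n)) / 10^total_scale
  new_transformed(vals, if (is.na(seed)) -1L else seed, total_scale)
}

# Exact decrypted mantissas as signed decimal strings (for integer-level
# equality checks against the plaintext big-integer product).
rp_decrypt_mantissas <- function(priv, enc_y) {
  dec <- paillier_decrypt(priv, enc_y)
  vapply(decode_signed_hex(dec$mantissa, priv$n), .bn_to_dec, "",
         USE.NAMES = FALSE)
}

#' Verify noninvertibility of a protected template
#'
#' Implements the underdetermined-system argument: an attacker holding the
#' matrix \eqn{M} and a transformed vector \eqn{y} must solve
#' \eqn{M^T x = y} for the original features \eqn{x}. When
#' `rank(M^T) = q < j` the system has infinitely many solutions, so the
#' original template cannot be recovered. The report carries the rank, the
#' underdetermined flag, and — as a constructive witness — two distinct
#' preimages `x` and `x + v` (with `v` in the null space of \eqn{M^T}) that
#' both project onto `y`.
#'
#' @param M a `projection_matrix`.
#' @param y a `transformed_vector` (or numeric vector) consistent with some
#'   preimage.
#' @param tol residual tolerance for consistency and witness checks.
#' @return a list: `rank`, `n_unknowns`, `underdetermined`, `consistent`,
#'   `witness_preimages` (list of two vectors, or `NULL`), `residuals`.
#' @export
rp_verify_noninvertibility <- function(M, y, tol = 1e-9) {
  stopifnot(inherits(M, "projection_matrix"))
  yv <- if (inherits(y, "transformed_vector")) y$values else as.numeric(y)
  A <- t(M$entries)                              # q x j coefficient matrix
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  rnk <- sum(sv$d > max(dim(A)) * max(sv$d) * .Machine$double.eps)
  under <- rnk < M$j
  # Minimum-norm particular solution via the pseudoinverse.
  dinv <- ifelse(sv$d > max(dim(A)) * max(sv$d) * .Machine$double.eps,
                 1 / sv$d, 0)
  x0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (dinv * (t(sv$u[, seq_along(sv$d), drop = FALSE]) %*% yv))
  x0 <- as.numeric(x0)
  res0 <- sqrt(sum((A %*% x0 - yv)^2))
  if (res0 > tol * max(1, sqrt(sum(yv^2)))) {
    return(list(rank = rnk, n_unknowns = M$j, underdetermined = under,
                consistent = FALSE, witness_preimages = NULL,
                residuals = res0))
  }
  witnesses <- NULL
  if (under) {
    nullsp <- sv$v[, (rnk + 1):ncol(sv$v), drop = FALSE]
    v <- as.numeric(nullsp[, 1])
    v <- v / sqrt(sum(v^2))
    x1 <- x0 + v
    witnesses <- list(x0, x1)
  }
  res <- vapply(witnesses %||% list(), function(x) {
    sqrt(sum((A %*% x - yv)^2))
  }, 0)
  list(rank = rnk, n_unknowns = M$j, underdetermined = under,
       consistent = TRUE, witness_preimages = witnesses,
       residuals = if (length(res)) res else res0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Renew (revoke and reissue) a projection matrix
#'
#' Renewability per ISO/IEC 24745: a compromised protected template is
#' revoked by drawing a fresh matrix of the same shape from a new seed; the
#' same gait features then yield a different transformed template.
#'
#' @param old a `projection_matrix`.
#' @param new_seed integer seed, different from `old$seed`.
#' @return a new `projection_matrix` with identical `(j, q)`.
#' @export
rp_renew <- function(old, new_seed) {
  stopifnot(inherits(old, "projection_matrix"))
  if (identical(as.integer(new_seed), old$seed)) {
    stop("renewal-noop error: new seed equals the current seed")
  }
  rp_generate(old$j, old$q, new_seed)
}

#' Persist a projection matrix as seed metadata
#'
#' Entries are regenerable from the seed, so only `(j, q, seed, scale)` is
#' stored.
#' @param M a `projection_matrix`.
#' @param path JSON path.
#' @param scale_exp quantization scale to record.
#' @return `path`, invisibly.
#' @export
write_projection <- function(M, path, scale_exp = 6L) {
  stopifnot(inherits(M, "projection_matrix"))
  jsonlite::write_json(
    list(type = "projection_matrix", j = M$j, q = M$q, seed = M$seed,
         scale_exp = as.integer(scale_exp)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "projection_matrix")) {
    stop("not a projection-matrix file: ", path)
  }
  rp_generate(obj$j, obj$q, obj$seed)
}
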