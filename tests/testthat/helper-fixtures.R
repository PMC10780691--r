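# Shared fixtures, built in code at test time.

# Toy keypair on the smallest interesting modulus n = 5 * 7 = 35.
toy_keypair <- function() keypair_from_primes(5, 7)

# Memoized reproducible keypairs so repeated tests don't regenerate primes.
.kp_cache <- new.env(parent = emptyenv())
test_keypair <- function(prime_bits = 64, seed = 424242) {
  key <- paste0("kp", prime_bits, "_", seed)
  if (is.null(.kp_cache[[key]])) {
    .kp_cache[[key]] <- generate_keypair(prime_bits, crypto_seed = seed)
  }
  .kp_cache[[key]]
}

# Encrypt a numeric vector under a keypair at a given fixed-point scale.
encrypt_vec <- function(x, kp, scale = 6L) {
  paillier_encrypt(kp$public, encode_real(x, scale, kp$public$n),
                   seeded_r = TRUE)
}

decrypt_vec <- function(ct, kp) {
  decode_real(paillier_decrypt(kp$private, ct), kp$private$n)
}

# A clean noiseless-ish walking sequence for feature tests.
test_walk <- function(n_frames = 120, class_label = "healthy", seed = 1,
                      noise_sd = 0, ...) {
  generate_walker(gait_profile(class_label, noise_sd = noise_sd, ...),
                  n_frames = n_frames, seed = seed)
}

# Straight-line constant-velocity track of all 14 keypoints.
linear_track <- function(n = 40, dt = 1 / 30, vx = 3, vy = 1) {
  base_x <- matrix(rep(seq(0, by = vx, length.out = n), 14), ncol = 14)
  base_y <- matrix(rep(seq(0, by = vy, length.out = n), 14), ncol = 14)
  offs <- seq(0, 130, by = 10)
  keypoint_sequence(sweep(base_x, 2, offs, "+"), sweep(base_y, 2, offs, "+"),
                    dt = dt)
}

# Raw residue encoding (full Z_n, bypassing the signed-range check) for
# exhaustive homomorphism tests, plus its numeric readback.
new_encoded_for_test <- function(f, n) {
  gaitshield:::new_encoded(gaitshield:::bn_from_int(f), 0L)
}
raw_mantissa <- function(enc) gaitshield:::bn_to_num(enc$mantissa)

# Exact big-integer matrix-vector product (plaintext reference route).
.bn_matvec_wrap <- function(x_hex, m_hex) gaitshield:::.bn_matvec(x_hex, m_hex)
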