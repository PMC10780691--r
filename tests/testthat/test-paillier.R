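test_that("key derivation on the worked toy primes matches modular arithmetic", {
  kp <- toy_keypair()
  expect_equal(bn_to_num(kp$public$n), 35)
  expect_equal(bn_to_num(kp$public$g), 36)
  expect_equal(bn_to_num(kp$private$lam), 24)
  # oracle: exhaustive search for the inverse of lambda = 24 in Z_35
  mu_oracle <- which((24 * (1:34)) %% 35 == 1)
  expect_equal(bn_to_num(kp$private$mu), mu_oracle)
  expect_equal(mu_oracle, 19)
})

test_that("lambda * mu is 1 mod n for generated keypairs", {
  for (bits in c(16, 32)) {
    kp <- generate_keypair(bits, crypto_seed = bits)
    prod_mod <- .bn_mod(.bn_mul(kp$private$lam, kp$private$mu), kp$public$n)
    expect_equal(bn_to_num(prod_mod), 1)
    expect_true(bn_eq(kp$public$g, .bn_add(kp$public$n, "1")))
  }
})

test_that("modulus bit length is exactly twice the prime size", {
  bits <- vapply(1:20, function(s) {
    .bn_bits(generate_keypair(16, crypto_seed = s)$public$n)
  }, 0L)
  expect_true(all(bits == 32L))
  kp <- test_keypair(64)
  expect_identical(.bn_bits(kp$public$n), 128L)
})

test_that("fixed-point encoding round-trips and rejects overflow", {
  n35 <- toy_keypair()$public$n
  expect_equal(bn_to_num(encode_real(0, 3, n35)$mantissa), 0)
  enc <- encode_real(-1.2, 1, n35)
  expect_equal(bn_to_num(enc$mantissa), 23)  # -12 mod 35
  expect_equal(decode_real(enc, n35), -1.2)
  # exhaustive in-range loop at scale 1
  for (x in seq(-1.7, 1.7, by = 0.1)) {
    expect_equal(decode_real(encode_real(x, 1, n35), n35), x)
  }
  expect_error(encode_real(1.8, 1, n35), "overflow")
  expect_error(encode_real(Inf, 1, n35), "non-finite")
})

test_that("encryption round-trips exhaustively on the toy modulus", {
  kp <- toy_keypair()
  n <- kp$public$n
  # all residues of Z_35 via the signed half-range [-17, 17]
  set.seed(1)
  for (f in -17:17) {
    ct <- paillier_encrypt(kp$public, encode_real(f, 0, n), seeded_r = TRUE)
    expect_equal(decode_real(paillier_decrypt(kp$private, ct), n), f)
  }
})

test_that("trivial ciphertext identities hold", {
  kp <- toy_keypair()
  n <- kp$public$n
  ct1 <- paillier_encrypt(kp$public, encode_real(0, 0, n), r = 1)
  expect_equal(bn_to_num(ct1$values), 1)  # g^0 * 1^n = 1
  expect_equal(decode_real(paillier_decrypt(kp$private, ct1), n), 0)
  expect_error(paillier_encrypt(kp$public, encode_real(1, 0, n), r = 35),
               "invalid-randomizer")
  expect_error(paillier_encrypt(kp$public, encode_real(1, 0, n), r = 5),
               "invalid-randomizer")  # gcd(5, 35) != 1
})

test_that("encryption is randomized", {
  kp <- test_keypair(32, seed = 7)
  n <- kp$public$n
  set.seed(99)
  cts <- replicate(100, {
    paillier_encrypt(kp$public, encode_real(3, 0, n), seeded_r = TRUE)$values
  })
  expect_gte(length(unique(cts)), 99)
})

test_that("additive homomorphism matches modular arithmetic on all toy pairs", {
  kp <- toy_keypair()
  n <- kp$public$n
  set.seed(2)
  cts <- lapply(0:34, function(f) {
    paillier_encrypt(kp$public, new_encoded_for_test(f, n), seeded_r = TRUE)
  })
  for (f1 in 0:34) {
    for (f2 in 0:34) {
      s <- add_encrypted(cts[[f1 + 1]], cts[[f2 + 1]], kp$public)
      got <- raw_mantissa(paillier_decrypt(kp$private, s))
      expect_equal(got, (f1 + f2) %% 35)  # oracle: direct mod arithmetic
    }
  }
})

test_that("scalar homomorphism matches modular arithmetic for k up to 6", {
  kp <- toy_keypair()
  n <- kp$public$n
  set.seed(3)
  for (f in 0:34) {
    ct <- paillier_encrypt(kp$public, new_encoded_for_test(f, n), seeded_r = TRUE)
    for (k in 0:6) {
      p <- scalar_multiply(ct, new_encoded_for_test(k, n), kp$public)
      expect_equal(raw_mantissa(paillier_decrypt(kp$private, p)),
                       (f * k) %% 35)
    }
  }
})

test_that("scalar identities: times one and times minus one", {
  kp <- test_keypair(32, seed = 7)
  n <- kp$public$n
  ct <- encrypt_vec(4.5, kp, scale = 3)
  one <- encode_real(1, 0, n)
  expect_equal(decrypt_vec(scalar_multiply(ct, one, kp$public), kp), 4.5)
  minus <- encode_real(-1, 0, n)
  expect_equal(decrypt_vec(scalar_multiply(ct, minus, kp$public), kp), -4.5)
})

test_that("a chain of 30 homomorphic additions counts to 30", {
  kp <- test_keypair(64)
  n <- kp$public$n
  set.seed(4)
  acc <- encrypt_vec(1, kp, scale = 0)
  for (i in 2:30) {
    acc <- add_encrypted(acc, encrypt_vec(1, kp, scale = 0), kp$public)
  }
  expect_equal(decrypt_vec(acc, kp), 30)
})

test_that("mismatched keys and scales are refused", {
  kp1 <- test_keypair(32, seed = 7)
  kp2 <- test_keypair(32, seed = 8)
  c1 <- encrypt_vec(1, kp1, scale = 2)
  c2 <- encrypt_vec(1, kp2, scale = 2)
  expect_error(add_encrypted(c1, c2, kp1$public), "key error")
  expect_error(paillier_decrypt(kp2$private, c1), "wrong-key")
  c3 <- encrypt_vec(1, kp1, scale = 3)
  expect_error(add_encrypted(c1, c3, kp1$public), "scale error")
})

test_that("keys and ciphertexts survive a JSON round trip", {
  kp <- test_keypair(32, seed = 7)
  td <- withr::local_tempdir()
  write_pubkey(kp$public, file.path(td, "pub.json"))
  write_privkey(kp$private, file.path(td, "prv.json"))
  pub2 <- read_pubkey(file.path(td, "pub.json"))
  prv2 <- read_privkey(file.path(td, "prv.json"))
  expect_identical(pub2$n, kp$public$n)
  expect_identical(prv2$mu, kp$private$mu)
  ct <- encrypt_vec(c(1.25, -3.5), kp)
  write_ctvec(ct, file.path(td, "ct.json"))
  ct2 <- read_ctvec(file.path(td, "ct.json"))
  expect_equal(decrypt_vec(ct2, kp), c(1.25, -3.5))
  expect_error(read_pubkey(file.path(td, "prv.json")), "not a public key")
})
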