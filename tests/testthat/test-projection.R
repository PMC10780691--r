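test_that("matrix generation is deterministic and seed-sensitive", {
  M1 <- rp_generate(30, 29, seed = 1)
  M2 <- rp_generate(30, 29, seed = 1)
  expect_identical(M1$entries, M2$entries)
  M3 <- rp_generate(30, 29, seed = 2)
  expect_gte(mean(M1$entries != M3$entries), 0.99)
})

test_that("entries follow the N(0, 1/q) law at sample level", {
  M <- rp_generate(1000, 100, seed = 123)
  se <- sqrt((1 / 100) / (1000 * 100))
  expect_lte(abs(mean(M$entries)), 4 * se)
  expect_lte(abs(stats::var(as.vector(M$entries)) - 0.01), 0.001)
})

test_that("plain projection equals the double-loop dot-product oracle", {
  set.seed(5)
  M <- rp_generate(5, 3, seed = 9)
  x <- rnorm(5)
  y <- rp_project(x, M)
  oracle <- numeric(3)
  for (k in 1:3) {
    for (i in 1:5) oracle[k] <- oracle[k] + x[i] * M$entries[i, k]
  }
  expect_equal(y$values, oracle, tolerance = 1e-12)
  expect_equal(rp_project(rep(0, 5), M)$values, rep(0, 3))
  # selection matrix: first q columns of the identity
  Mi <- rp_generate(4, 2, seed = 1)
  Mi$entries <- diag(4)[, 1:2]
  expect_equal(rp_project(c(7, 8, 9, 10), Mi)$values, c(7, 8))
  expect_error(rp_project(rep(0, 6), M), "length mismatch")
})

test_that("quantization rounds and dequantizes within half an ulp", {
  M <- rp_generate(20, 10, seed = 3)
  Mq0 <- rp_quantize(M, 0)
  expect_identical(Mq0$mantissas, round(M$entries))
  M$entries[1, 1] <- 0.1234567
  Mq <- rp_quantize(M, 6)
  expect_identical(Mq$mantissas[1, 1], 123457)
  expect_lte(max(abs(rp_dequantize(Mq) - M$entries)), 5e-7)
})

test_that("the overflow guard is strict and exact", {
  kp128 <- test_keypair(64)
  expect_true(overflow_bound_ok(kp128$public, 30, 6, 6, 1e3, 10))
  kp_toy <- toy_keypair()
  expect_false(overflow_bound_ok(kp_toy$public, 30, 6, 6, 1e3, 10))
  # boundary: product exactly (n-1)/2 must be rejected
  n <- bn_to_num(kp_toy$public$n)          # 35 -> (n-1)/2 = 17
  expect_false(overflow_bound_ok(kp_toy$public, 1, 0, 0, 17, 1))
  expect_true(overflow_bound_ok(kp_toy$public, 1, 0, 0, 16, 1))
})

test_that("encrypted projection agrees with the plaintext route", {
  kp <- test_keypair(64)
  M <- rp_generate(8, 7, seed = 21)
  Mq <- rp_quantize(M, 6)
  set.seed(6)
  x <- rnorm(8) * 5
  ex <- encrypt_vec(x, kp, scale = 6)
  ey <- rp_project_encrypted(ex, Mq, kp$public)
  y <- rp_decrypt_transformed(kp$private, ey)
  expect_equal(y$values, rp_project(x, M)$values, tolerance = 1e-3)
  # exact integer-level agreement with the big-integer mantissa product
  got <- gaitshield:::rp_decrypt_mantissas(kp$private, ey)
  xm <- gaitshield:::bn_from_int(round(x * 1e6))
  mm <- matrix(gaitshield:::bn_from_int(as.vector(Mq$mantissas)),
               nrow = 8, ncol = 7)
  want <- vapply(.bn_matvec_wrap(xm, mm), gaitshield:::.bn_to_dec, "")
  expect_identical(got, unname(want))
  # zero vector protects to zero
  e0 <- encrypt_vec(rep(0, 8), kp, scale = 6)
  y0 <- rp_decrypt_transformed(kp$private,
                               rp_project_encrypted(e0, Mq, kp$public))
  expect_equal(y0$values, rep(0, 7))
})

test_that("transformed vectors are identical across distinct keypairs", {
  M <- rp_generate(6, 5, seed = 33)
  Mq <- rp_quantize(M, 6)
  set.seed(7)
  x <- rnorm(6)
  outs <- lapply(c(101, 102), function(s) {
    kp <- test_keypair(64, seed = s)
    ex <- encrypt_vec(x, kp, scale = 6)
    gaitshield:::rp_decrypt_mantissas(
      kp$private, rp_project_encrypted(ex, Mq, kp$public))
  })
  expect_identical(outs[[1]], outs[[2]])
})

test_that("noninvertibility report finds rank deficiency and preimage witnesses", {
  set.seed(8)
  M <- rp_generate(5, 3, seed = 41)
  x <- rnorm(5)
  y <- rp_project(x, M)
  rep <- rp_verify_noninvertibility(M, y)
  expect_identical(rep$rank, 3L)
  expect_identical(rep$n_unknowns, 5L)
  expect_true(rep$underdetermined)
  expect_true(rep$consistent)
  w <- rep$witness_preimages
  expect_gt(sqrt(sum((w[[1]] - w[[2]])^2)), 1e-6)
  for (wx in w) {
    expect_lt(max(abs(rp_project(wx, M)$values - y$values)), 1e-9)
  }
})

test_that("square full-rank systems are reported invertible", {
  M <- rp_generate(4, 4, seed = 2)
  y <- rp_project(c(1, 2, 3, 4), M)
  rep <- rp_verify_noninvertibility(M, y)
  expect_false(rep$underdetermined)
  expect_identical(rep$rank, 4L)
})

test_that("inconsistent targets are flagged without witnesses", {
  M <- rp_generate(3, 3, seed = 2)
  M$entries[, 3] <- M$entries[, 2]   # rank 2, q = 3
  rep <- rp_verify_noninvertibility(M, c(0, 1, 5))
  expect_false(rep$consistent)
  expect_null(rep$witness_preimages)
})

test_that("renewal changes the template but preserves shape and determinism", {
  M <- rp_generate(10, 9, seed = 1)
  expect_error(rp_renew(M, 1), "renewal-noop")
  M2 <- rp_renew(M, 2)
  expect_identical(c(M2$j, M2$q), c(M$j, M$q))
  set.seed(9)
  x <- rnorm(10)
  d <- sqrt(sum((rp_project(x, M)$values - rp_project(x, M2)$values)^2))
  expect_gt(d, 0)
  M2b <- rp_renew(M, 2)
  expect_identical(M2$entries, M2b$entries)
})

test_that("projection matrices persist as seed metadata", {
  td <- withr::local_tempdir()
  M <- rp_generate(7, 6, seed = 55)
  write_projection(M, file.path(td, "m.json"))
  M2 <- read_projection(file.path(td, "m.json"))
  expect_identical(M$entries, M2$entries)
})
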