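test_that("the bilinear attention score matches a triple-loop oracle", {
  set.seed(21)
  W <- matrix(rnorm(16), 4, 4)
  h_t <- rnorm(4)
  h_s <- rnorm(4)
  oracle <- 0
  for (i in 1:4) for (j in 1:4) oracle <- oracle + h_t[i] * W[i, j] * h_s[j]
  expect_equal(attention_score(h_t, h_s, W), oracle, tolerance = 1e-12)
  expect_equal(attention_score(h_t, h_s, diag(4)), sum(h_t * h_s))
  expect_equal(attention_score(rep(0, 4), h_s, W), 0)
  expect_error(attention_score(rnorm(3), h_s, W), "dimension mismatch")
})

test_that("softmax outputs are probabilities and inference is deterministic", {
  set.seed(22)
  cfg <- model_config(lstm_units = 6, dense_units = 4, train_seed = 2)
  seqs <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  m <- build_model(3, cfg)
  p1 <- predict_lstm(structure(list(params = m$params, cfg = cfg,
                                    input_dim = 3L), class = "lstm_model"),
                     seqs)
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
  p2 <- predict_lstm(structure(list(params = m$params, cfg = cfg,
                                    input_dim = 3L), class = "lstm_model"),
                     seqs)
  expect_identical(p1, p2)
})

test_that("the parameter count follows the layer arithmetic", {
  cfg <- model_config()
  # hand count: gates (C+H)*4H + 4H, attention H^2, dense H*10+10, out 10*2+2
  C <- 15; H <- 32
  hand <- (C + H) * 4 * H + 4 * H + H * H + H * 10 + 10 + 10 * 2 + 2
  expect_equal(count_parameters(C, cfg), hand)
  m <- build_model(C, cfg)
  expect_equal(sum(vapply(m$params, length, 0L)), hand)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(23)
  cfg <- model_config(lstm_units = 4, dense_units = 3, dropout_rate = 0,
                      l1 = 0.002, train_seed = 3)
  m <- build_model(3, cfg)
  params <- m$params
  params$cfg_l1 <- cfg$l1
  TT <- 5; B <- 2
  X <- array(rnorm(TT * B * 3), c(TT, B, 3))
  mask <- matrix(1, TT, B)
  mask[5, 2] <- 0                     # ragged batch
  y <- rbind(c(1, 0), c(0, 1))
  fwd <- gaitshield:::lstm_forward(params, X, mask)
  gr <- gaitshield:::lstm_backward(params, fwd, y)
  eps <- 1e-6
  for (nm in names(gr)) {
    p <- params[[nm]]
    idx <- sample(length(p), min(5, length(p)))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (gaitshield:::lstm_loss(pp, gaitshield:::lstm_forward(pp, X, mask), y, cfg$l1) -
              gaitshield:::lstm_loss(pm, gaitshield:::lstm_forward(pm, X, mask), y, cfg$l1)) /
        (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training learns a linearly separable toy sequence problem", {
  set.seed(24)
  mk <- function(shift) matrix(rnorm(20 * 2, mean = shift, sd = 0.3), 20, 2)
  seqs <- c(lapply(1:10, function(i) mk(0)), lapply(1:10, function(i) mk(1.5)))
  labels <- rep(c(0L, 1L), each = 10)
  cfg <- model_config(lstm_units = 8, dense_units = 4, epochs = 60,
                      batch_size = 8, dropout_rate = 0.1, train_seed = 5)
  m <- train_lstm(seqs, labels, cfg)
  prob <- predict_lstm(m, seqs)[, 2]
  expect_gte(mean((prob >= 0.5) == labels), 0.95)
  # training is reproducible under the same seed
  m2 <- train_lstm(seqs, labels, cfg)
  expect_identical(m$params, m2$params)
})

test_that("confusion-matrix metrics match hand-computed values", {
  # TP=3, FP=1, FN=1, TN=5
  y_true <- c(rep(1, 4), rep(0, 6))
  y_prob <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.4)
  m <- compute_metrics(y_true, y_prob)
  expect_equal(m$precision, 75)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 83.33, tolerance = 1e-3)
  expect_equal(m$accuracy, 80)
  f1_hand <- 2 * 0.75 * 0.75 / (0.75 + 0.75) * 100
  expect_equal(m$f1, f1_hand)
})

test_that("perfect separation scores 100 on every metric", {
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  for (v in unlist(m)) expect_equal(v, 100)
})

test_that("AUC matches pROC and tends to 50% for random scores", {
  skip_if_not_installed("pROC")
  set.seed(25)
  y <- rbinom(200, 1, 0.5)
  p <- runif(200)
  ours <- compute_metrics(y, p)$auc_roc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        levels = c(0, 1),
                                        direction = "<"))) * 100
  expect_equal(ours, ref, tolerance = 1e-9)
  expect_lt(abs(ours - 50), 15)
  expect_warning(compute_metrics(rep(1, 5), runif(5)), "AUC undefined")
})

test_that("interpatient folds are subject-disjoint, balanced and seeded", {
  labels <- setNames(rep(c("healthy", "dementia"), c(23, 20)),
                     c(sprintf("H%02d", 1:23), sprintf("P%02d", 1:20)))
  plan <- cv_plan(n_folds = 20, seed = 3)
  folds <- interpatient_split(labels, plan)
  expect_length(folds, 20)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(f$train, 28)  # 14 + 14
    expect_length(f$test, 15)   # 43 - 28
    expect_identical(sum(labels[f$train] == "healthy"), 14L)
    expect_identical(sum(labels[f$train] == "dementia"), 14L)
  }
  folds2 <- interpatient_split(labels, cv_plan(n_folds = 20, seed = 3))
  expect_identical(folds, folds2)
  # proportional fallback below 15 subjects per class
  small <- setNames(rep(c("healthy", "dementia"), c(10, 10)),
                    c(sprintf("H%d", 1:10), sprintf("P%d", 1:10)))
  fsm <- interpatient_split(small, cv_plan(n_folds = 3, seed = 1))
  expect_length(fsm[[1]]$train, 14)  # 7 + 7
  tiny <- setNames(rep(c("healthy", "dementia"), c(1, 1)), c("a", "b"))
  expect_error(interpatient_split(tiny, cv_plan(2, train_per_class = 1)),
               "too few subjects")
})

test_that("an information-preserving square projection leaves accuracy intact", {
  # protection with q = j and an identity-like (square, full-rank) matrix is
  # a rotation of the feature space; the paired ablation should show ~0 delta
  coh <- generate_cohort(4, 4, recordings_per_subject = 2, n_frames = 50,
                         seed = 30, missing_rate = 0, spike_rate = 0)
  cfg <- model_config(epochs = 30, train_seed = 4, batch_size = 8)
  plan <- cv_plan(n_folds = 2, train_per_class = 2, seed = 5)
  res <- run_ablation(coh, cfg, plan, protection = "both",
                      proj_dim_q = 15L, encrypted = FALSE, clean = FALSE)
  expect_lt(abs(res$delta$accuracy), 25)
  expect_identical(res$fold_digest, res$fold_digest)
})

test_that("paired arms share folds and reproduce exactly under fixed seeds", {
  coh <- generate_cohort(3, 3, recordings_per_subject = 2, n_frames = 40,
                         seed = 31, missing_rate = 0, spike_rate = 0)
  cfg <- model_config(epochs = 10, train_seed = 6, batch_size = 4)
  plan <- cv_plan(n_folds = 2, train_per_class = 2, seed = 7)
  r1 <- run_ablation(coh, cfg, plan, encrypted = FALSE, clean = FALSE)
  r2 <- run_ablation(coh, cfg, plan, encrypted = FALSE, clean = FALSE)
  expect_identical(r1$unprotected$per_fold, r2$unprotected$per_fold)
  expect_identical(r1$protected$per_fold, r2$protected$per_fold)
  expect_identical(r1$fold_digest, r2$fold_digest)
})

test_that("the encrypted and plaintext protection routes agree in the harness", {
  coh <- generate_cohort(2, 2, recordings_per_subject = 1, n_frames = 30,
                         seed = 32, missing_rate = 0, spike_rate = 0)
  cfg <- model_config(epochs = 5, train_seed = 8, batch_size = 4)
  plan <- cv_plan(n_folds = 1, train_per_class = 1, seed = 9)
  re <- run_ablation(coh, cfg, plan, protection = "on", encrypted = TRUE,
                     crypto_seed = 3, clean = FALSE)
  rp <- run_ablation(coh, cfg, plan, protection = "on", encrypted = FALSE,
                     crypto_seed = 3, clean = FALSE)
  expect_equal(re$protected$per_fold, rp$protected$per_fold, tolerance = 1e-6)
})
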