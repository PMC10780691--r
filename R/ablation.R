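#' Protected-versus-unprotected ablation harness
#'
#' Reproduces the design of the reference evaluation on synthetic cohorts:
#' the same interpatient cross-validation is run twice with identical fold
#' assignments, initialization and training seeds — once on raw gait
#' channels, once with the hybrid protection (Paillier encryption, then
#' Gaussian random projection executed in the ciphertext domain with a
#' fresh matrix per fold, then decryption of the transformed channels)
#' inserted between feature extraction and the classifier. The difference
#' table Delta = protected - unprotected per metric quantifies the cost of
#' protection.
#'
#' @name ablation
NULL

#' Protect a per-frame channel matrix through the encrypted pipeline
#'
#' Each frame's length-`j` channel vector is fixed-point encoded,
#' encrypted, projected in the ciphertext domain through the quantized
#' matrix, and decrypted to a length-`q` transformed vector. The overflow
#' guard is checked before any ciphertext work starts.
#'
#' @param channels `T x j` numeric matrix.
#' @param Mq a `quantized_projection_matrix` with `Mq$j == ncol(channels)`.
#' @param pub,priv Paillier keypair.
#' @param feat_scale fixed-point scale for the features (default 6).
#' @param seeded_r draw encryption randomizers from R's seedable RNG.
#' @return `T x q` numeric matrix of transformed channels.
#' @export
protect_channels <- function(channels, Mq, pub, priv, feat_scale = 6L,
                             seeded_r = TRUE) {
  stopifnot(inherits(Mq, "quantized_projection_matrix"),
            ncol(channels) == Mq$j)
  tf <- nrow(channels)
  max_feat <- max(abs(channels), 1e-12)
  max_entry <- max(abs(Mq$mantissas)) / 10^Mq$scale_exp
  if (!overflow_bound_ok(pub, Mq$j, feat_scale, Mq$scale_exp,
                         max_feat, max(max_entry, 1e-12))) {
    stop("overflow error: modulus too small for these channels and scales")
  }
  enc <- encode_real(as.vector(t(channels)), feat_scale, pub$n)
  ct <- paillier_encrypt(pub, enc, seeded_r = seeded_r)
  ct_mat <- matrix(ct$values, nrow = tf, ncol = Mq$j, byrow = TRUE)
  exp_hex <- matrix(
    vapply(as.vector(Mq$mantissas),
           function(m) .bn_mod(bn_from_int(m), pub$n), ""),
    nrow = Mq$j, ncol = Mq$q)
  proj <- .paillier_project_mat(pub$n_sq, ct_mat, exp_hex)
  dec <- .paillier_decrypt_vec(priv$n, pub$n_sq, priv$lam, priv$mu,
                               as.vector(proj))
  vals <- bn_to_num(decode_signed_hex(dec, priv$n)) /
    10^(feat_scale + Mq$scale_exp)
  matrix(vals, nrow = tf, ncol = Mq$q)
}

# Channel matrices + labels for every recording of a cohort.
cohort_channels <- function(cohort, clean = TRUE) {
  seqs <- lapply(cohort$recordings, function(r) {
    s <- if (clean) clean_sequence(r$seq) else r$seq
    gait_channel_matrix(s)
  })
  labels <- vapply(cohort$recordings, function(r) {
    as.integer(r$class_label == "dementia")
  }, 0L)
  subjects <- vapply(cohort$recordings, `[[`, "", "subject_id")
  list(channels = seqs, labels = labels, subjects = subjects)
}

#' Run the paired protected / unprotected experiment
#'
#' @param cohort a `synthetic_cohort`.
#' @param cfg a [model_config()].
#' @param plan a [cv_plan()].
#' @param protection `"both"` (default), `"off"` or `"on"`.
#' @param proj_dim_q transformed length; default `j - 1` where `j` is the
#'   number of gait channels.
#' @param prime_bits Paillier prime size for the protected arm (default 64,
#'   i.e. a 128-bit modulus).
#' @param crypto_seed seed for the reproducible test keypair.
#' @param feat_scale,mat_scale fixed-point scales (default 6 / 6).
#' @param encrypted run the protection through the real ciphertext-domain
#'   pipeline (default `TRUE`); `FALSE` uses the algebraically identical
#'   quantized plaintext projection (useful for quick experiments; the
#'   equivalence of the two routes is itself a tested property).
#' @param clean apply the cleaning pipeline to each recording first.
#' @param verbose print per-fold progress.
#' @return a list with `unprotected` and/or `protected` (each holding
#'   `per_fold` data frame and `mean` list), `delta` (protected minus
#'   unprotected mean per metric, when both arms ran), and `fold_digest`
#'   (hash of fold assignments + training seeds, identical across arms by
#'   construction).
#' @export
run_ablation <- function(cohort, cfg = model_config(), plan = cv_plan(),
                         protection = c("both", "off", "on"),
                         proj_dim_q = NULL, prime_bits = 64L,
                         crypto_seed = 1L, feat_scale = 6L, mat_scale = 6L,
                         encrypted = TRUE, clean = TRUE, verbose = FALSE) {
  protection <- match.arg(protection)
  dat <- cohort_channels(cohort, clean = clean)
  if (length(unique(dat$labels)) < 2) stop("cohort must contain both classes")
  subject_labels <- vapply(
    split(ifelse(dat$labels == 1, "dementia", "healthy"), dat$subjects),
    `[[`, "", 1)
  folds <- interpatient_split(subject_labels, plan)
  j <- ncol(dat$channels[[1]])
  q <- proj_dim_q %||% (j - 1L)
  fold_digest <- .sha256_hex(paste(
    vapply(folds, function(f) paste(sort(f$train), collapse = ","), ""),
    cfg$train_seed, collapse = ";"))

  arms <- switch(protection, both = c("off", "on"), off = "off", on = "on")
  kp <- NULL
  if ("on" %in% arms) {
    kp <- generate_keypair(prime_bits, crypto_seed = crypto_seed)
  }
  run_arm <- function(protected) {
    rows <- NULL
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      chans <- dat$channels
      if (protected) {
        M <- rp_generate(j, q, seed = fold$projection_seed)
        Mq <- rp_quantize(M, mat_scale)
        chans <- lapply(chans, function(ch) {
          if (encrypted) {
            protect_channels(ch, Mq, kp$public, kp$private,
                             feat_scale = feat_scale)
          } else {
            (round(ch * 10^feat_scale) %*% Mq$mantissas) /
              10^(feat_scale + mat_scale)
          }
        })
      }
      tr <- which(dat$subjects %in% fold$train)
      te <- which(dat$subjects %in% fold$test)
      fold_cfg <- cfg
      fold_cfg$train_seed <- cfg$train_seed + f
      model <- train_lstm(chans[tr], dat$labels[tr], fold_cfg)
      prob <- predict_lstm(model, chans[te])[, 2]
      m <- suppressWarnings(compute_metrics(dat$labels[te], prob))
      rows <- rbind(rows, data.frame(fold = f, precision = m$precision,
                                     sensitivity = m$sensitivity,
                                     specificity = m$specificity,
                                     f1 = m$f1, accuracy = m$accuracy,
                                     auc_roc = m$auc_roc))
      if (verbose) {
        message(sprintf("%s arm fold %d: accuracy %.1f%%",
                        if (protected) "protected" else "unprotected",
                        f, m$accuracy))
      }
    }
    list(per_fold = rows,
         mean = as.list(colMeans(rows[, -1, drop = FALSE], na.rm = TRUE)))
  }
  out <- list(fold_digest = fold_digest)
  if ("off" %in% arms) out$unprotected <- run_arm(FALSE)
  if ("on" %in% arms) out$protected <- run_arm(TRUE)
  if (all(c("off", "on") %in% arms)) {
    out$delta <- Map(function(p, u) p - u,
                     out$protected$mean, out$unprotected$mean)
  }
  out
}
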