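#' LSTM classifier with multiplicative attention
#'
#' The diagnosis network is a single LSTM layer (32 units), dropout (rate
#' 0.3) on the hidden-state sequence, a multiplicative attention layer with
#' trained bilinear score
#' \deqn{\mathrm{score}(h_t, h_s) = h_t^{\top} W h_s,}
#' a 10-unit dense layer with rectified-linear activation and an L1 penalty
#' of 0.002 on its weights, and a 2-way softmax output, trained with
#' RMSProp on binary cross-entropy. The attention wiring is Luong-style:
#' the query is the last hidden state, scores over all hidden states are
#' softmax-normalized and the resulting context vector feeds the dense
#' stack. The network is implemented directly in R (forward pass and
#' backpropagation through time), so training is fully deterministic under
#' a seed.
#'
#' @name lstm-attention
NULL

#' Classifier configuration
#'
#' Defaults mirror the reference architecture: 32 LSTM units, dropout 0.3,
#' 10 dense units with L1 0.002, 2-way softmax, RMSProp, binary
#' cross-entropy. Epochs, batch size and learning rate are training-side
#' choices (100 / 16 / 0.001 by default; early stopping deliberately off
#' so that paired protected/unprotected runs remain comparable).
#'
#' @param lstm_units,dropout_rate,dense_units,l1 architecture settings.
#' @param epochs,batch_size,learning_rate,rho RMSProp training settings.
#' @param clip_norm global gradient-norm clip (stabilizes BPTT).
#' @param train_seed seed for initialization, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(lstm_units = 32L, dropout_rate = 0.3,
                         dense_units = 10L, l1 = 0.002,
                         epochs = 100L, batch_size = 16L,
                         learning_rate = 1e-3, rho = 0.9,
                         clip_norm = 5, train_seed = 1L) {
  structure(list(lstm_units = as.integer(lstm_units),
                 dropout_rate = dropout_rate,
                 dense_units = as.integer(dense_units), l1 = l1,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, rho = rho,
                 clip_norm = clip_norm, train_seed = as.integer(train_seed)),
            class = "model_config")
}

#' Multiplicative attention score
#'
#' The bilinear form \eqn{h_t^\top W h_s} between a query state and a
#' source state.
#'
#' @param h_t,h_s numeric vectors (query / source hidden states).
#' @param W square weight matrix conforming with both.
#' @return a single number.
#' @export
attention_score <- function(h_t, h_s, W) {
  if (length(h_t) != nrow(W) || length(h_s) != ncol(W)) {
    stop("dimension mismatch in attention score")
  }
  as.numeric(t(h_t) %*% W %*% h_s)
}

# Glorot-uniform init helper.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' @param input_dim number of input channels.
#' @param cfg a [model_config()].
#' @param seed init seed (defaults to `cfg$train_seed`).
#' @return a `lstm_model` parameter list.
#' @export
build_model <- function(input_dim, cfg = model_config(), seed = NULL) {
  H <- cfg$lstm_units
  D <- cfg$dense_units
  with_local_seed(seed %||% cfg$train_seed, {
    params <- list(
      Wg = glorot(input_dim + H, 4 * H),      # [i | f | g | o] gate weights
      bg = {
        b <- numeric(4 * H)
        b[(H + 1):(2 * H)] <- 1               # forget-gate bias at 1
        b
      },
      Wa = diag(H) + glorot(H, H) * 0.1,      # attention bilinear form
      Wd = glorot(H, D), bd = numeric(D),
      Wo = glorot(D, 2), bo = numeric(2))
    structure(list(params = params, cfg = cfg, input_dim = as.integer(input_dim)),
              class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("LSTM-attention classifier: %d channels -> %d units -> %d dense -> 2 softmax (%d parameters)\n",
              x$input_dim, x$cfg$lstm_units, x$cfg$dense_units, np))
  invisible(x)
}

#' Parameter count of the architecture
#' @param input_dim input channels.
#' @param cfg a [model_config()].
#' @return integer total number of trainable scalars.
#' @export
count_parameters <- function(input_dim, cfg = model_config()) {
  H <- cfg$lstm_units
  D <- cfg$dense_units
  (input_dim + H) * 4 * H + 4 * H +  # gates
    H * H +                          # attention
    H * D + D +                      # dense
    D * 2 + 2                        # output
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# Forward pass over a batch. X: T x B x C array; mask: T x B (1 = valid).
# Dropout masks (T x B x H) are applied to the hidden states seen by the
# attention/readout path only, not to the recurrence.
lstm_forward <- function(params, X, mask, drop_mask = NULL) {
  dims <- dim(X)
  TT <- dims[1]; B <- dims[2]; C <- dims[3]
  H <- ncol(params$Wa)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  hs <- array(0, c(TT, B, H))     # raw hidden states
  cs <- array(0, c(TT, B, H))
  gates <- array(0, c(TT, B, 4 * H))
  for (t in seq_len(TT)) {
    z <- cbind(matrix(X[t, , ], B, C), h)
    a <- z %*% params$Wg + matrix(params$bg, B, 4 * H, byrow = TRUE)
    i_g <- sigmoid(a[, 1:H, drop = FALSE])
    f_g <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g_g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    h_new <- o_g * tanh(c_new)
    m <- mask[t, ]
    cc <- c_new * m + cc * (1 - m)
    h <- h_new * m + h * (1 - m)
    hs[t, , ] <- h
    cs[t, , ] <- cc
    gates[t, , ] <- cbind(i_g, f_g, g_g, o_g)
  }
  # dropout on the readout path
  hd <- if (is.null(drop_mask)) hs else hs * drop_mask
  # attention: query = hidden state at each sample's last valid step
  last_idx <- apply(mask, 2, function(m) max(which(m > 0)))
  q <- t(vapply(seq_len(B), function(b) hd[last_idx[b], b, ], numeric(H)))
  qW <- q %*% params$Wa                       # B x H
  scores <- matrix(-Inf, TT, B)
  for (t in seq_len(TT)) {
    scores[t, ] <- rowSums(qW * matrix(hd[t, , ], B, H))
  }
  scores[mask == 0] <- -Inf
  alpha <- apply(scores, 2, function(s) {
    e <- exp(s - max(s[is.finite(s)]))
    e[!is.finite(e)] <- 0
    e / sum(e)
  })                                          # TT x B
  context <- matrix(0, B, H)
  for (t in seq_len(TT)) {
    context <- context + alpha[t, ] * matrix(hd[t, , ], B, H)
  }
  zd <- context %*% params$Wd + matrix(params$bd, B, length(params$bd), byrow = TRUE)
  relu <- pmax(zd, 0)
  logits <- relu %*% params$Wo + matrix(params$bo, B, 2, byrow = TRUE)
  probs <- softmax_rows(logits)
  list(hs = hs, cs = cs, gates = gates, hd = hd, q = q, qW = qW,
       alpha = alpha, context = context, zd = zd, relu = relu,
       logits = logits, probs = probs, last_idx = last_idx,
       X = X, mask = mask, drop_mask = drop_mask)
}

# Backward pass: gradients of mean cross-entropy (+ L1 on Wd) w.r.t. params.
lstm_backward <- function(params, fwd, y_onehot) {
  X <- fwd$X; mask <- fwd$mask
  dims <- dim(X)
  TT <- dims[1]; B <- dims[2]; C <- dims[3]
  H <- ncol(params$Wa)
  dlogits <- (fwd$probs - y_onehot) / B
  gWo <- t(fwd$relu) %*% dlogits
  gbo <- colSums(dlogits)
  drelu <- dlogits %*% t(params$Wo)
  dzd <- drelu * (fwd$zd > 0)
  gWd <- t(fwd$context) %*% dzd + params$cfg_l1 * sign(params$Wd)
  gbd <- colSums(dzd)
  dcontext <- dzd %*% t(params$Wd)            # B x H
  # attention backward
  dalpha <- matrix(0, TT, B)
  dhd <- array(0, c(TT, B, H))
  for (t in seq_len(TT)) {
    ht <- matrix(fwd$hd[t, , ], B, H)
    dalpha[t, ] <- rowSums(dcontext * ht)
    dhd[t, , ] <- dhd[t, , ] + fwd$alpha[t, ] * dcontext
  }
  # softmax over time (per sample)
  sum_ad <- colSums(fwd$alpha * dalpha)
  dscores <- fwd$alpha * sweep(dalpha, 2, sum_ad)
  dscores[mask == 0] <- 0
  gWa <- matrix(0, H, H)
  dq <- matrix(0, B, H)
  for (t in seq_len(TT)) {
    ht <- matrix(fwd$hd[t, , ], B, H)
    ds <- dscores[t, ]
    gWa <- gWa + t(fwd$q) %*% (ds * ht)
    dq <- dq + (ds * ht) %*% t(params$Wa)
    dhd[t, , ] <- dhd[t, , ] + ds * fwd$qW
  }
  # query gradient lands on the last valid step
  for (b in seq_len(B)) {
    dhd[fwd$last_idx[b], b, ] <- dhd[fwd$last_idx[b], b, ] + dq[b, ]
  }
  # through dropout
  if (!is.null(fwd$drop_mask)) dhd <- dhd * fwd$drop_mask
  # BPTT
  gWg <- matrix(0, C + H, 4 * H)
  gbg <- numeric(4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in TT:1) {
    m <- mask[t, ]
    dh <- matrix(dhd[t, , ], B, H) + dh_next
    dc <- dc_next
    # masked steps: state carried through unchanged
    dh_skip <- dh * (1 - m)
    dc_skip <- dc * (1 - m)
    dh <- dh * m
    dc <- dc * m
    i_g <- matrix(fwd$gates[t, , 1:H], B, H)
    f_g <- matrix(fwd$gates[t, , (H + 1):(2 * H)], B, H)
    g_g <- matrix(fwd$gates[t, , (2 * H + 1):(3 * H)], B, H)
    o_g <- matrix(fwd$gates[t, , (3 * H + 1):(4 * H)], B, H)
    c_t <- matrix(fwd$cs[t, , ], B, H)
    c_prev <- if (t > 1) matrix(fwd$cs[t - 1, , ], B, H) else matrix(0, B, H)
    h_prev <- if (t > 1) matrix(fwd$hs[t - 1, , ], B, H) else matrix(0, B, H)
    tc <- tanh(c_t)
    do_g <- dh * tc
    dc <- dc + dh * o_g * (1 - tc^2)
    di <- dc * g_g
    dg <- dc * i_g
    df <- dc * c_prev
    dc_prev <- dc * f_g
    da <- cbind(di * i_g * (1 - i_g),
                df * f_g * (1 - f_g),
                dg * (1 - g_g^2),
                do_g * o_g * (1 - o_g))
    z <- cbind(matrix(X[t, , ], B, C), h_prev)
    gWg <- gWg + t(z) %*% da
    gbg <- gbg + colSums(da)
    dz <- da %*% t(params$Wg)
    dh_next <- dz[, (C + 1):(C + H), drop = FALSE] + dh_skip
    dc_next <- dc_prev + dc_skip
  }
  list(Wg = gWg, bg = gbg, Wa = gWa, Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

# mean cross-entropy + L1 penalty (for gradient checking / monitoring)
lstm_loss <- function(params, fwd, y_onehot, l1) {
  ce <- -mean(rowSums(y_onehot * log(pmax(fwd$probs, 1e-12))))
  ce + l1 * sum(abs(params$Wd))
}

# Pad a list of T_i x C matrices into a TT x B x C array plus mask.
pad_sequences <- function(seqs) {
  TT <- max(vapply(seqs, nrow, 0L))
  B <- length(seqs)
  C <- ncol(seqs[[1]])
  X <- array(0, c(TT, B, C))
  mask <- matrix(0, TT, B)
  for (b in seq_len(B)) {
    tb <- nrow(seqs[[b]])
    X[seq_len(tb), b, ] <- as.matrix(seqs[[b]])
    mask[seq_len(tb), b] <- 1
  }
  list(X = X, mask = mask)
}

#' Train the classifier
#'
#' RMSProp on binary (2-way softmax) cross-entropy with the L1 penalty on
#' the dense layer; minibatches are reshuffled every epoch and dropout
#' masks are redrawn per batch, all from `cfg$train_seed`, so a run is
#' exactly reproducible.
#'
#' @param sequences list of `T_i x C` channel matrices.
#' @param labels integer vector (0 = first class, 1 = second class).
#' @param cfg a [model_config()].
#' @param standardize z-score channels using statistics of these training
#'   sequences (stored on the model and re-applied at prediction).
#' @param verbose print the loss every 20 epochs.
#' @return a trained `lstm_model`.
#' @export
train_lstm <- function(sequences, labels, cfg = model_config(),
                       standardize = TRUE, verbose = FALSE) {
  stopifnot(length(sequences) == length(labels), length(sequences) >= 2)
  C <- ncol(sequences[[1]])
  stats_mu <- rep(0, C); stats_sd <- rep(1, C)
  if (standardize) {
    all_rows <- do.call(rbind, sequences)
    stats_mu <- colMeans(all_rows)
    stats_sd <- apply(all_rows, 2, stats::sd)
    stats_sd[!is.finite(stats_sd) | stats_sd < 1e-8] <- 1
    sequences <- lapply(sequences, function(s) {
      sweep(sweep(s, 2, stats_mu), 2, stats_sd, "/")
    })
  }
  model <- build_model(C, cfg)
  params <- model$params
  params$cfg_l1 <- cfg$l1
  cache <- lapply(params[names(params) != "cfg_l1"], function(p) p * 0)
  y_onehot_all <- cbind(1 - labels, labels)
  n <- length(sequences)
  with_local_seed(cfg$train_seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        pad <- pad_sequences(sequences[idx])
        drop_mask <- NULL
        if (cfg$dropout_rate > 0) {
          dm <- array(stats::rbinom(length(pad$mask) * cfg$lstm_units, 1,
                                    1 - cfg$dropout_rate),
                      c(dim(pad$X)[1], dim(pad$X)[2], cfg$lstm_units))
          drop_mask <- dm / (1 - cfg$dropout_rate)
        }
        fwd <- lstm_forward(params, pad$X, pad$mask, drop_mask)
        grads <- lstm_backward(params, fwd, y_onehot_all[idx, , drop = FALSE])
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
        if (is.finite(gnorm) && gnorm > cfg$clip_norm) {
          grads <- lapply(grads, function(g) g * cfg$clip_norm / gnorm)
        }
        for (nm in names(grads)) {
          cache[[nm]] <- cfg$rho * cache[[nm]] + (1 - cfg$rho) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * grads[[nm]] / (sqrt(cache[[nm]]) + 1e-8)
        }
      }
      if (verbose && ep %% 20 == 0) {
        pad <- pad_sequences(sequences)
        fwd <- lstm_forward(params, pad$X, pad$mask)
        message(sprintf("epoch %d loss %.4f", ep,
                        lstm_loss(params, fwd, y_onehot_all, cfg$l1)))
      }
    }
  })
  params$cfg_l1 <- NULL
  model$params <- params
  model$stats_mu <- stats_mu
  model$stats_sd <- stats_sd
  model
}

#' Predict class probabilities
#'
#' Dropout is disabled at inference, so repeated predictions are
#' deterministic.
#'
#' @param model a trained `lstm_model`.
#' @param sequences list of `T_i x C` matrices.
#' @return `n x 2` matrix of class probabilities (rows sum to 1).
#' @export
predict_lstm <- function(model, sequences) {
  stopifnot(inherits(model, "lstm_model"))
  if (!is.null(model$stats_mu)) {
    sequences <- lapply(sequences, function(s) {
      sweep(sweep(s, 2, model$stats_mu), 2, model$stats_sd, "/")
    })
  }
  pad <- pad_sequences(sequences)
  fwd <- lstm_forward(model$params, pad$X, pad$mask)
  fwd$probs
}
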