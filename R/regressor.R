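# Shallow multi-task regressor: embedding -> [emb x 128] -> [128 x 64] ->
# two [64 x 1] heads for intelligibility (INT) and severity (SEV). Each
# hidden block is linear -> batch norm -> ReLU -> dropout; heads are affine
# with inference-time clamping to the 0-10 clinical scale. Trained with Adam
# on the 50/50-weighted sum of per-task MSE losses.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Training configuration
#'
#' Defaults are the deployed recipe: Adam, learning rate 0.001, batch size 8,
#' dropout 0.2, 20 epochs, equal task weights.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the data (no early stopping).
#' @param dropout dropout rate on hidden blocks, in [0, 1).
#' @param loss_weights length-2 weights (INT, SEV); must sum to 1.
#' @param seed seed controlling shuffling, dropout and initialization.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 8L,
                            epochs = 20L, dropout = 0.2,
                            loss_weights = c(0.5, 0.5), seed = 1L) {
  ps_validate(learning_rate > 0 && batch_size >= 1 && epochs >= 1,
              "learning_rate, batch_size and epochs must be positive")
  ps_validate(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  ps_validate(length(loss_weights) == 2L && all(loss_weights >= 0) &&
                abs(sum(loss_weights) - 1) < 1e-9,
              "loss_weights must be two non-negative values summing to 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 loss_weights = as.numeric(loss_weights),
                 optimizer = "adam", seed = as.integer(seed)),
            class = "training_config")
}

#' Initialize regressor weights
#'
#' @param seed integer seed.
#' @param emb_dim embedding dimension (512 for x-vectors).
#' @return object of class \code{regressor_weights}.
#' @export
init_regressor_weights <- function(seed, emb_dim = 512L) {
  glorot <- function(din, dout) {
    matrix(stats::rnorm(din * dout, 0, sqrt(2 / (din + dout))), din, dout)
  }
  bn_new <- function(d) list(gamma = rep(1, d), beta = numeric(d),
                             run_mean = numeric(d), run_var = rep(1, d))
  w <- with_seed(seed, list(
    emb_dim = as.integer(emb_dim),
    W1 = glorot(emb_dim, 128L), b1 = numeric(128L), bn1 = bn_new(128L),
    W2 = glorot(128L, 64L),     b2 = numeric(64L),  bn2 = bn_new(64L),
    W_int = glorot(64L, 1L), b_int = 0,
    W_sev = glorot(64L, 1L), b_sev = 0
  ))
  structure(w, class = "regressor_weights")
}

bn_forward <- function(h, bn, train) {
  if (train) {
    mu <- colMeans(h)
    v <- colMeans(h^2) - mu^2
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  xhat <- sweep(sweep(h, 2L, mu), 2L, sqrt(v + BN_EPS), `/`)
  list(out = sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`),
       xhat = xhat, mu = mu, var = v)
}

bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  inv_sd <- 1 / sqrt(cache$var + BN_EPS)
  term <- n * dxhat -
    matrix(colSums(dxhat), n, ncol(dy), byrow = TRUE) -
    cache$xhat * matrix(colSums(dxhat * cache$xhat), n, ncol(dy), byrow = TRUE)
  list(dx = sweep(term, 2L, inv_sd / n, `*`),
       dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

#' Forward pass of the multi-task regressor
#'
#' In \code{infer} mode dropout is disabled, batch norm uses running
#' statistics, and outputs are clamped to [0, 10]; the pass is then
#' deterministic. In \code{train} mode batch statistics and (seeded, caller's
#' RNG) dropout masks are used and raw head outputs are returned.
#'
#' @param x embedding vector (length \code{emb_dim}) or matrix
#'   (n x \code{emb_dim}).
#' @param w \code{regressor_weights}.
#' @param mode \code{"infer"} or \code{"train"}.
#' @param dropout dropout rate used in train mode.
#' @return data.frame with columns \code{int}, \code{sev} (infer mode), or a
#'   list \code{(pred, cache)} in train mode.
#' @export
reg_forward <- function(x, w, mode = c("infer", "train"), dropout = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(w, "regressor_weights"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != w$emb_dim) {
    ps_stop(sprintf("embedding dimension %d does not match model emb_dim %d",
                    ncol(x), w$emb_dim), "ps_config_error")
  }
  train <- mode == "train"
  cache <- list(x = x)

  a1 <- sweep(x %*% w$W1, 2L, w$b1, `+`)
  bn1 <- bn_forward(a1, w$bn1, train)
  r1 <- pmax(bn1$out, 0)
  if (train && dropout > 0) {
    m1 <- matrix(stats::runif(length(r1)) >= dropout, nrow(r1), ncol(r1)) /
      (1 - dropout)
    h1 <- r1 * m1
  } else { m1 <- NULL; h1 <- r1 }

  a2 <- sweep(h1 %*% w$W2, 2L, w$b2, `+`)
  bn2 <- bn_forward(a2, w$bn2, train)
  r2 <- pmax(bn2$out, 0)
  if (train && dropout > 0) {
    m2 <- matrix(stats::runif(length(r2)) >= dropout, nrow(r2), ncol(r2)) /
      (1 - dropout)
    h2 <- r2 * m2
  } else { m2 <- NULL; h2 <- r2 }

  p_int <- drop(h2 %*% w$W_int) + w$b_int
  p_sev <- drop(h2 %*% w$W_sev) + w$b_sev

  if (!train) {
    return(data.frame(int = clamp01_10(p_int), sev = clamp01_10(p_sev)))
  }
  cache <- c(cache, list(bn1 = bn1, r1 = r1, m1 = m1, h1 = h1,
                         bn2 = bn2, r2 = r2, m2 = m2, h2 = h2))
  list(pred = cbind(int = p_int, sev = p_sev), cache = cache)
}

#' Multi-task loss
#'
#' Weighted sum of the per-task mean squared errors:
#' \code{w_int * MSE(INT) + w_sev * MSE(SEV)}.
#'
#' @param pred,target matrices or data.frames with columns \code{int},
#'   \code{sev}, equal non-zero length.
#' @param weights length-2 task weights.
#' @return scalar loss.
#' @export
multitask_loss <- function(pred, target, weights = c(0.5, 0.5)) {
  pred <- as.matrix(as.data.frame(pred)[, c("int", "sev")])
  target <- as.matrix(as.data.frame(target)[, c("int", "sev")])
  ps_validate(nrow(pred) > 0L, "empty batch")
  ps_validate(nrow(pred) == nrow(target),
              "prediction and target batches differ in length")
  ps_validate(length(weights) == 2L, "weights must have length 2")
  weights[1L] * mean((pred[, 1L] - target[, 1L])^2) +
    weights[2L] * mean((pred[, 2L] - target[, 2L])^2)
}

# gradient of the weighted multi-task MSE w.r.t. predictions
loss_grad <- function(pred, target, weights) {
  n <- nrow(pred)
  cbind(2 * weights[1L] * (pred[, 1L] - target[, 1L]) / n,
        2 * weights[2L] * (pred[, 2L] - target[, 2L]) / n)
}

backward <- function(dpred, w, cache) {
  g <- list()
  d_int <- dpred[, 1L, drop = FALSE]
  d_sev <- dpred[, 2L, drop = FALSE]
  g$W_int <- crossprod(cache$h2, d_int); g$b_int <- sum(d_int)
  g$W_sev <- crossprod(cache$h2, d_sev); g$b_sev <- sum(d_sev)
  dh2 <- d_int %*% t(w$W_int) + d_sev %*% t(w$W_sev)
  if (!is.null(cache$m2)) dh2 <- dh2 * cache$m2
  dr2 <- dh2 * (cache$r2 > 0)
  bb2 <- bn_backward(dr2, cache$bn2, w$bn2$gamma)
  g$gamma2 <- bb2$dgamma; g$beta2 <- bb2$dbeta
  g$W2 <- crossprod(cache$h1, bb2$dx); g$b2 <- colSums(bb2$dx)
  dh1 <- bb2$dx %*% t(w$W2)
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  dr1 <- dh1 * (cache$r1 > 0)
  bb1 <- bn_backward(dr1, cache$bn1, w$bn1$gamma)
  g$gamma1 <- bb1$dgamma; g$beta1 <- bb1$dbeta
  g$W1 <- crossprod(cache$x, bb1$dx); g$b1 <- colSums(bb1$dx)
  g
}

# flat list of trainable parameter names, mirrored in the Adam state
.param_names <- c("W1", "b1", "gamma1", "beta1", "W2", "b2", "gamma2",
                  "beta2", "W_int", "b_int", "W_sev", "b_sev")

get_param <- function(w, nm) {
  switch(nm, gamma1 = w$bn1$gamma, beta1 = w$bn1$beta,
         gamma2 = w$bn2$gamma, beta2 = w$bn2$beta, w[[nm]])
}
set_param <- function(w, nm, val) {
  if (nm == "gamma1") w$bn1$gamma <- val
  else if (nm == "beta1") w$bn1$beta <- val
  else if (nm == "gamma2") w$bn2$gamma <- val
  else if (nm == "beta2") w$bn2$beta <- val
  else w[[nm]] <- val
  w
}

#' Train the multi-task regressor
#'
#' Runs exactly \code{cfg$epochs} epochs of Adam over seeded shuffled
#' mini-batches of \code{cfg$batch_size}, minimizing the weighted sum of
#' per-task MSEs. Fully reproducible for a fixed \code{cfg$seed}.
#'
#' @param data a training set as returned by
#'   \code{\link{cohort_to_training_table}}: list with \code{embeddings}
#'   (n x emb matrix) and \code{targets} (data.frame with \code{int},
#'   \code{sev} in [0, 10]).
#' @param cfg a \code{\link{training_config}}.
#' @param init_weights optional starting \code{regressor_weights}; defaults
#'   to a fresh initialization from \code{cfg$seed}.
#' @return list with \code{weights} (trained \code{regressor_weights}) and
#'   \code{loss_trace} (mean mini-batch loss per epoch).
#' @export
train_regressor <- function(data, cfg = training_config(),
                            init_weights = NULL) {
  stopifnot(inherits(cfg, "training_config"))
  X <- as.matrix(data$embeddings)
  Yd <- as.data.frame(data$targets)
  ps_validate(nrow(X) > 0L, "empty training data")
  ps_validate(nrow(X) >= cfg$batch_size,
              "need at least one full mini-batch of examples")
  ps_validate(all(Yd$int >= 0 & Yd$int <= 10 & Yd$sev >= 0 & Yd$sev <= 10),
              "targets must lie in [0, 10]")
  Y <- cbind(int = Yd$int, sev = Yd$sev)
  n <- nrow(X)

  w <- if (is.null(init_weights)) init_regressor_weights(cfg$seed, ncol(X))
       else init_weights
  if (ncol(X) != w$emb_dim) {
    ps_stop("embedding dimension does not match initial weights",
            "ps_config_error")
  }

  # Adam state
  mm <- lapply(.param_names, function(nm) get_param(w, nm) * 0)
  vv <- mm
  names(mm) <- names(vv) <- .param_names
  lr <- cfg$learning_rate; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- numeric(cfg$epochs)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        fw <- reg_forward(X[idx, , drop = FALSE], w, mode = "train",
                          dropout = cfg$dropout)
        loss <- multitask_loss(fw$pred, Y[idx, , drop = FALSE],
                               cfg$loss_weights)
        if (!is.finite(loss)) {
          ps_stop(sprintf("training diverged (non-finite loss) at epoch %d",
                          epoch), "ps_divergence_error")
        }
        batch_losses[bi] <- loss
        # update batch-norm running statistics
        for (k in 1:2) {
          bnm <- paste0("bn", k)
          cc <- fw$cache[[bnm]]
          w[[bnm]]$run_mean <- (1 - BN_MOMENTUM) * w[[bnm]]$run_mean +
            BN_MOMENTUM * cc$mu
          w[[bnm]]$run_var <- (1 - BN_MOMENTUM) * w[[bnm]]$run_var +
            BN_MOMENTUM * cc$var
        }
        grads <- backward(loss_grad(fw$pred, Y[idx, , drop = FALSE],
                                    cfg$loss_weights),
                          w, fw$cache)
        step <- step + 1L
        for (nm in .param_names) {
          gr <- grads[[nm]]
          mm[[nm]] <- beta1 * mm[[nm]] + (1 - beta1) * gr
          vv[[nm]] <- beta2 * vv[[nm]] + (1 - beta2) * gr^2
          mhat <- mm[[nm]] / (1 - beta1^step)
          vhat <- vv[[nm]] / (1 - beta2^step)
          w <- set_param(w, nm, get_param(w, nm) - lr * mhat / (sqrt(vhat) + eps))
        }
      }
      trace[epoch] <- mean(batch_losses)
    }
  })
  list(weights = w, loss_trace = trace)
}

#' Predict scores for embeddings
#'
#' @param x embedding vector or matrix.
#' @param w trained \code{regressor_weights}.
#' @return data.frame with \code{int} and \code{sev} in [0, 10].
#' @export
predict_scores <- function(x, w) reg_forward(x, w, mode = "infer")

#' Predict the score pair for one recording
#'
#' Embeds the recording (whole-passage strategy) or each of its eight
#' segments (mean of per-segment predictions), then applies the regressor.
#' Results are clamped to [0, 10].
#'
#' @param w a \code{waveform}.
#' @param extractor \code{extractor_weights}.
#' @param reg trained \code{regressor_weights}.
#' @param strategy \code{"whole"} (default) or \code{"segments"}.
#' @param breaks break specification for the segments strategy.
#' @return named numeric vector \code{c(int = ..., sev = ...)}.
#' @export
predict_recording <- function(w, extractor, reg,
                              strategy = c("whole", "segments"),
                              breaks = default_break_spec()) {
  strategy <- match.arg(strategy)
  if (strategy == "whole") {
    emb <- extract_embedding(w, extractor)
    p <- predict_scores(emb, reg)
    return(c(int = p$int[1L], sev = p$sev[1L]))
  }
  segs <- segment_passage(w, breaks)
  waves <- segment_audio(w, segs)
  preds <- vapply(waves, function(sw) {
    p <- predict_scores(extract_embedding(sw, extractor), reg)
    c(p$int[1L], p$sev[1L])
  }, numeric(2L))
  c(int = clamp01_10(mean(preds[1L, ])), sev = clamp01_10(mean(preds[2L, ])))
}

#' Speaker-disjoint split
#'
#' Splits speaker identifiers so that augmented copies of one speaker can
#' never straddle the train/validation boundary.
#'
#' @param speaker_ids character vector of unique speaker identifiers.
#' @param prop_train fraction assigned to training.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} id vectors.
#' @export
split_speakers <- function(speaker_ids, prop_train = 0.8, seed = 1L) {
  ids <- unique(speaker_ids)
  ps_validate(length(ids) >= 2L, "need at least two speakers to split")
  n_train <- max(1L, round(prop_train * length(ids)))
  with_seed(seed, {
    tr <- sample(ids, n_train)
    list(train = tr, test = setdiff(ids, tr))
  })
}
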