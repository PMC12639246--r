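# ---- losses -----------------------------------------------------------------

loss_value <- function(err, kind, delta = 1) {
  switch(kind,
    mse = err^2,
    mae = abs(err),
    huber = ifelse(abs(err) <= delta, 0.5 * err^2, delta * (abs(err) - 0.5 * delta)))
}

loss_grad <- function(err, kind, delta = 1) {
  switch(kind,
    mse = 2 * err,
    mae = sign(err),
    huber = pmax(pmin(err, delta), -delta))
}

# ---- regression head --------------------------------------------------------
# three (dropout, linear) stages with ReLU between stages and a rectified
# single-unit output: x -> drop -> W1 -> relu -> drop -> W2 -> relu -> drop
# -> W3 -> relu -> score

relu <- function(x) pmax(x, 0)

head_init <- function(din, hidden, label_mean) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(
    W1 = matrix(rnorm(din * h1, sd = sqrt(2 / din)), din, h1),
    b1 = numeric(h1),
    W2 = matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(rnorm(h2, sd = sqrt(2 / h2)), h2, 1),
    # start the output at the mean training label so the final ReLU is live
    b3 = label_mean)
}

head_forward <- function(head, x, masks = NULL) {
  x0 <- if (is.null(masks)) x else x * masks[[1]]
  z1 <- drop(crossprod(head$W1, x0)) + head$b1
  a1 <- relu(z1)
  x1 <- if (is.null(masks)) a1 else a1 * masks[[2]]
  z2 <- drop(crossprod(head$W2, x1)) + head$b2
  a2 <- relu(z2)
  x2 <- if (is.null(masks)) a2 else a2 * masks[[3]]
  z3 <- sum(head$W3 * x2) + head$b3
  list(pred = max(z3, 0), x0 = x0, z1 = z1, x1 = x1, z2 = z2, x2 = x2,
       z3 = z3, masks = masks)
}

head_backward <- function(head, cache, dpred, grads) {
  dz3 <- dpred * (cache$z3 > 0)
  grads$W3 <- grads$W3 + dz3 * cache$x2
  grads$b3 <- grads$b3 + dz3
  dx2 <- dz3 * drop(head$W3)
  da2 <- if (is.null(cache$masks)) dx2 else dx2 * cache$masks[[3]]
  dz2 <- da2 * (cache$z2 > 0)
  grads$W2 <- grads$W2 + outer(cache$x1, dz2)
  grads$b2 <- grads$b2 + dz2
  dx1 <- drop(head$W2 %*% dz2)
  da1 <- if (is.null(cache$masks)) dx1 else dx1 * cache$masks[[2]]
  dz1 <- da1 * (cache$z1 > 0)
  grads$W1 <- grads$W1 + outer(cache$x0, dz1)
  grads$b1 <- grads$b1 + dz1
  dx0 <- drop(head$W1 %*% dz1)
  grads$.dx <- if (is.null(cache$masks)) dx0 else dx0 * cache$masks[[1]]
  grads
}

make_masks <- function(dims, p) {
  if (p <= 0) return(NULL)
  keep <- 1 - p
  lapply(dims, function(d) (runif(d) >= p) / keep)
}

zero_like <- function(par) lapply(par, function(p) p * 0)

# decoupled weight-decay Adam; decay applied to weight matrices only
adamw_step <- function(par, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    decay <- if (nm %in% c("b1", "b2", "b3")) 0 else wd
    par[[nm]] <- par[[nm]] - lr * (upd + decay * par[[nm]])
  }
  list(par = par, state = state)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a sequence-pair binding-affinity regressor
#'
#' Trains a Siamese regression network on labelled sequence pairs: both
#' chains pass through one weight-shared per-residue encoder, the per-chain
#' embedding matrices are max-pooled into fixed-length vectors, fused by a
#' Hadamard product (so the prediction is invariant to chain order), and
#' mapped to a single non-negative affinity score in kcal/mol by a small
#' rectified regression head. With `encoder = "bilstm"` a frozen
#' bidirectional-LSTM baseline is used instead: the final hidden states of
#' the two chains are concatenated (order-sensitive) and only the head is
#' trained.
#'
#' Optimization is mini-batch AdamW with a selectable loss (squared error,
#' absolute error or Huber); all stochastic components (initialization,
#' shuffling, dropout) are keyed to `seed`, so identical calls reproduce
#' identical fits. Per-epoch training and validation loss/MAE curves are
#' retained in the returned object (`$history`, see [plot.affinity_model()]).
#'
#' @param data a `processed_dataset` from [build_dataset()] or
#'   [make_affinity_dataset()] (its train/validation split is used), or a
#'   data.frame with columns `seq_a`, `seq_b`, `label` (all rows train).
#' @param encoder `"tiny"`, `"bilstm"`, or a `pairbind_encoder` object
#'   (e.g. [precomputed_encoder()]).
#' @param loss `"mse"`, `"mae"` or `"huber"`.
#' @param embed_dim embedding dimension of the tiny encoder.
#' @param hidden the two hidden widths of the regression head.
#' @param dropout dropout probability before each linear stage.
#' @param epochs,batch_size,lr,weight_decay optimizer hyperparameters.
#' @param huber_delta transition point of the Huber loss (kcal/mol).
#' @param seed seed fixing every stochastic component of the fit.
#' @param max_len maximum sequence length accepted by the tiny encoder.
#' @param long_seq what to do with sequences longer than `max_len`:
#'   `"error"` (default) or `"truncate"`.
#' @param validation optional data.frame (`seq_a`, `seq_b`, `label`) used as
#'   the validation set when `data` is a bare data.frame.
#' @param verbose print per-epoch metrics.
#' @return an object of class `affinity_model` with `print`, `summary`,
#'   `predict`, `plot`, `residuals`, `fitted` and `coef` methods.
#' @examples
#' spec <- synthetic_complex_spec(seed = 7, len_a = 20, len_b = 20)
#' ds <- make_affinity_dataset(spec, n_pairs = 40)
#' fit <- affinity_model(ds, embed_dim = 8, hidden = c(16, 8), epochs = 3)
#' predict(fit, data.frame(seq_a = spec$seq_a, seq_b = spec$seq_b))
#' @export
affinity_model <- function(data, encoder = c("tiny", "bilstm"),
                           loss = c("mse", "mae", "huber"),
                           embed_dim = 32, hidden = c(512, 128), dropout = 0.1,
                           epochs = 30, batch_size = 32, lr = 1e-3,
                           weight_decay = 1e-4, huber_delta = 1,
                           seed = 1, max_len = 512,
                           long_seq = c("error", "truncate"),
                           validation = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  long_seq <- match.arg(long_seq)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0,
            dropout >= 0, dropout < 1, length(hidden) == 2)

  if (inherits(data, "processed_dataset")) {
    train <- data$records[data$train_idx, , drop = FALSE]
    val <- data$records[data$val_idx, , drop = FALSE]
  } else {
    stopifnot(is.data.frame(data),
              all(c("seq_a", "seq_b", "label") %in% names(data)))
    train <- data
    val <- validation
  }
  if (nrow(train) == 0L) stop("empty training split")
  if (!is.null(val) && nrow(val) == 0L) val <- NULL

  if (is.character(encoder)) {
    encoder <- switch(match.arg(encoder),
      tiny = tiny_encoder(embed_dim = embed_dim, max_len = max_len, seed = seed),
      bilstm = bilstm_encoder(max_len = max_len, seed = seed))
  }
  stopifnot(inherits(encoder, "pairbind_encoder"))
  trainable <- identical(encoder$mode, "trainable")

  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_rng)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(seed)

  clip_seq <- function(s) {
    if (!is.null(encoder$max_len) && nchar(s) > encoder$max_len) {
      if (long_seq == "error")
        stop(sprintf("sequence of length %d exceeds encoder max_len %d",
                     nchar(s), encoder$max_len))
      s <- substr(s, 1L, encoder$max_len)
    }
    s
  }
  ia_tr <- lapply(vapply(train$seq_a, clip_seq, character(1)), encode_seq)
  ib_tr <- lapply(vapply(train$seq_b, clip_seq, character(1)), encode_seq)
  y_tr <- train$label
  n_tr <- nrow(train)
  din <- if (encoder$fusion == "hadamard") encoder$embed_dim else 2L * encoder$embed_dim

  # frozen encoders: pair features never change, compute them once
  feats_tr <- feats_val <- NULL
  if (!trainable) {
    pair_feature <- function(sa, sb) frozen_pair_feature(encoder, sa, sb, clip_seq)
    feats_tr <- t(mapply(pair_feature, train$seq_a, train$seq_b))
    if (!is.null(val)) feats_val <- t(mapply(pair_feature, val$seq_a, val$seq_b))
  }

  head <- head_init(din, hidden, mean(y_tr))
  par <- if (trainable) c(head, encoder$params) else head
  state <- list(m = zero_like(par), v = zero_like(par))
  mask_dims <- c(din, hidden[1], hidden[2])

  # eval-mode forward for a training/validation example
  eval_pred <- function(ia, ib, feats, i, par_now) {
    if (trainable) {
      enc <- list(E = par_now$E, S = par_now$S)
      f <- fuse_hadamard(pool_max(tiny_embed(enc, ia[[i]])),
                         pool_max(tiny_embed(enc, ib[[i]])))
      head_forward(par_now, f)$pred
    } else {
      head_forward(par_now, feats[i, ])$pred
    }
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_mae = numeric(0), val_loss = numeric(0),
                        val_mae = numeric(0))
  step <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n_tr)
    run_loss <- 0; run_mae <- 0
    for (batch in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- zero_like(par)
      m <- length(batch)
      for (i in batch) {
        masks <- make_masks(mask_dims, dropout)
        if (trainable) {
          enc <- list(E = par$E, S = par$S)
          Ma <- tiny_embed(enc, ia_tr[[i]])
          Mb <- tiny_embed(enc, ib_tr[[i]])
          pa <- pool_max_with_argmax(Ma)
          pb <- pool_max_with_argmax(Mb)
          f <- fuse_hadamard(pa$value, pb$value)
          cache <- head_forward(par, f, masks)
        } else {
          cache <- head_forward(par, feats_tr[i, ], masks)
        }
        err <- cache$pred - y_tr[i]
        l <- loss_value(err, loss, huber_delta)
        if (!is.finite(l))
          stop(sprintf("non-finite %s loss at epoch %d (example %d, pred=%g, label=%g)",
                       loss, epoch, i, cache$pred, y_tr[i]))
        run_loss <- run_loss + l
        run_mae <- run_mae + abs(err)
        grads <- head_backward(par, cache, loss_grad(err, loss, huber_delta) / m, grads)
        if (trainable) {
          df <- grads$.dx
          du <- df * pb$value
          dv <- df * pa$value
          jd <- seq_len(din)
          ra <- pa$argmax; rb <- pb$argmax
          aa <- ia_tr[[i]][ra]; ab <- ib_tr[[i]][rb]
          # route the pooled gradient to the argmax residues of each chain
          grads$E[cbind(aa, jd)] <- grads$E[cbind(aa, jd)] + du * par$S[cbind(ra, jd)]
          grads$S[cbind(ra, jd)] <- grads$S[cbind(ra, jd)] + du * par$E[cbind(aa, jd)]
          grads$E[cbind(ab, jd)] <- grads$E[cbind(ab, jd)] + dv * par$S[cbind(rb, jd)]
          grads$S[cbind(rb, jd)] <- grads$S[cbind(rb, jd)] + dv * par$E[cbind(ab, jd)]
        }
      }
      grads$.dx <- NULL
      step <- step + 1L
      upd <- adamw_step(par, grads, state, lr, weight_decay, step)
      par <- upd$par; state <- upd$state
    }
    val_loss <- val_mae <- NA_real_
    if (!is.null(val)) {
      if (trainable) {
        iva <- lapply(vapply(val$seq_a, clip_seq, character(1)), encode_seq)
        ivb <- lapply(vapply(val$seq_b, clip_seq, character(1)), encode_seq)
        pv <- vapply(seq_len(nrow(val)), function(i)
          eval_pred(iva, ivb, NULL, i, par), numeric(1))
      } else {
        pv <- vapply(seq_len(nrow(val)), function(i)
          eval_pred(NULL, NULL, feats_val, i, par), numeric(1))
      }
      ev <- pv - val$label
      val_loss <- mean(loss_value(ev, loss, huber_delta))
      val_mae <- mean(abs(ev))
    }
    history[epoch, ] <- list(epoch, run_loss / n_tr, run_mae / n_tr,
                             val_loss, val_mae)
    if (verbose)
      message(sprintf("epoch %3d  train %s %.4f  mae %.4f  val %s %s  mae %s",
                      epoch, loss, run_loss / n_tr, run_mae / n_tr, loss,
                      format(val_loss, digits = 4), format(val_mae, digits = 4)))
  }

  if (trainable) {
    encoder$params$E <- par$E
    encoder$params$S <- par$S
  }
  fit <- structure(list(
    encoder = encoder,
    head = par[c("W1", "b1", "W2", "b2", "W3", "b3")],
    loss = loss, huber_delta = huber_delta,
    config = list(embed_dim = encoder$embed_dim, hidden = hidden,
                  dropout = dropout, epochs = epochs, batch_size = batch_size,
                  lr = lr, weight_decay = weight_decay, seed = seed,
                  max_len = encoder$max_len, long_seq = long_seq),
    history = history, train = train, val = val,
    call = match.call()),
    class = "affinity_model")
  fit
}

# pair feature for frozen encoders (bilstm concat / precomputed hadamard)
frozen_pair_feature <- function(encoder, sa, sb, clip_seq = identity) {
  if (encoder$name == "bilstm") {
    c(bilstm_encode(encoder$params, encode_seq(clip_seq(sa))),
      bilstm_encode(encoder$params, encode_seq(clip_seq(sb))))
  } else if (encoder$name == "precomputed") {
    tab <- encoder$params$tab
    if (is.null(tab[[sa]]) || is.null(tab[[sb]]))
      stop("no precomputed embedding for one of the input sequences")
    fuse_hadamard(pool_max(tab[[sa]]), pool_max(tab[[sb]]))
  } else stop("unknown frozen encoder: ", encoder$name)
}

# ---- prediction -------------------------------------------------------------

#' Predict binding affinity for sequence pairs
#'
#' Deterministic evaluation-mode forward pass: dropout is disabled and every
#' prediction is a non-negative affinity score in kcal/mol. For the Siamese
#' (Hadamard-fused) encoders the prediction is bit-for-bit invariant to
#' swapping `seq_a` and `seq_b`; the BiLSTM baseline is order-sensitive by
#' construction.
#'
#' @param object an [affinity_model()] fit.
#' @param newdata data.frame with columns `seq_a` and `seq_b`; defaults to
#'   the validation split (or training split when no validation exists).
#' @param chunked use overlapping-chunk averaged inference
#'   ([chunked_predict()]); the default for the BiLSTM baseline is `FALSE`
#'   here so that the two strategies can be compared explicitly.
#' @param chunk_len,stride chunking scheme when `chunked = TRUE`.
#' @param ... unused.
#' @return numeric vector of non-negative scores.
#' @export
predict.affinity_model <- function(object, newdata = NULL, chunked = FALSE,
                                   chunk_len = 100, stride = 50, ...) {
  if (is.null(newdata)) newdata <- if (!is.null(object$val)) object$val else object$train
  stopifnot(all(c("seq_a", "seq_b") %in% names(newdata)))
  vapply(seq_len(nrow(newdata)), function(i) {
    if (chunked)
      chunked_predict(object, newdata$seq_a[i], newdata$seq_b[i],
                      chunk_len = chunk_len, stride = stride)
    else predict_pair(object, newdata$seq_a[i], newdata$seq_b[i])
  }, numeric(1))
}

predict_pair <- function(object, seq_a, seq_b) {
  enc <- object$encoder
  if (!is.null(enc$max_len)) {
    too_long <- max(nchar(seq_a), nchar(seq_b)) > enc$max_len
    if (too_long && object$config$long_seq == "error")
      stop(sprintf("sequence exceeds encoder max_len %d (set long_seq='truncate' or use chunked inference)",
                   enc$max_len))
    if (too_long) {
      seq_a <- substr(seq_a, 1, enc$max_len)
      seq_b <- substr(seq_b, 1, enc$max_len)
    }
  }
  x <- if (enc$name == "tiny") {
    fuse_hadamard(pool_max(tiny_embed(enc$params, encode_seq(seq_a))),
                  pool_max(tiny_embed(enc$params, encode_seq(seq_b))))
  } else {
    frozen_pair_feature(enc, seq_a, seq_b)
  }
  head_forward(object$head, x)$pred
}

#' Overlapping-chunk windows of a sequence
#'
#' Enumerates the sliding windows used by chunked inference: starts at
#' `0, stride, 2*stride, ...` (0-based) while the start is below
#' `L - (chunk_len - stride)`, with the final window truncated at the
#' sequence end. A sequence no longer than `chunk_len` yields a single
#' window covering the whole sequence. Every residue is covered by at least
#' one window; with the default 100/50 scheme every interior residue is
#' covered exactly twice.
#'
#' @param L sequence length.
#' @param chunk_len window length (default 100 residues).
#' @param stride distance between window starts (default 50).
#' @return data.frame with 1-based `start`, `end` and a `ragged` flag for
#'   the truncated final window.
#' @export
chunk_windows <- function(L, chunk_len = 100, stride = 50) {
  stopifnot(L >= 1, chunk_len >= 1, stride >= 1, stride <= chunk_len)
  limit <- max(L - (chunk_len - stride), 1)
  starts <- as.integer(seq(0L, by = stride, length.out = ceiling(limit / stride)))
  ends <- as.integer(pmin(starts + chunk_len, L))
  data.frame(start = starts + 1L, end = ends, ragged = ends - starts < chunk_len)
}

#' Chunked sequence-pair prediction
#'
#' Splits both sequences into overlapping windows (default 100 residues with
#' a 50-residue stride), scores every chunk-of-A x chunk-of-B combination
#' with the fitted model, and returns the arithmetic mean. This removes the
#' positional bias of recurrent encoders toward sequence starts and lets any
#' model score sequences longer than its nominal maximum length.
#'
#' @param object an [affinity_model()] fit.
#' @param seq_a,seq_b the sequence pair.
#' @param chunk_len,stride chunking scheme; see [chunk_windows()].
#' @return mean affinity score over all chunk pairs (non-negative).
#' @export
chunked_predict <- function(object, seq_a, seq_b, chunk_len = 100, stride = 50) {
  wa <- chunk_windows(nchar(seq_a), chunk_len, stride)
  wb <- chunk_windows(nchar(seq_b), chunk_len, stride)
  preds <- numeric(0)
  for (i in seq_len(nrow(wa)))
    for (j in seq_len(nrow(wb)))
      preds <- c(preds, predict_pair(object,
                                     substr(seq_a, wa$start[i], wa$end[i]),
                                     substr(seq_b, wb$start[j], wb$end[j])))
  mean(preds)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.affinity_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<affinity_model: encoder '%s' (d=%d, %s), loss=%s, %d epochs>\n",
              x$encoder$name, x$encoder$embed_dim, x$encoder$mode,
              x$loss, nrow(x$history)))
  cat(sprintf("  train: %d pairs, final %s %.4f, MAE %.4f kcal/mol\n",
              nrow(x$train), x$loss, h$train_loss, h$train_mae))
  if (!is.null(x$val))
    cat(sprintf("  val:   %d pairs, final %s %.4f, MAE %.4f kcal/mol\n",
                nrow(x$val), x$loss, h$val_loss, h$val_mae))
  invisible(x)
}

#' @export
summary.affinity_model <- function(object, ...) {
  h <- object$history[nrow(object$history), ]
  out <- list(encoder = object$encoder$name, loss = object$loss,
              epochs = nrow(object$history),
              n_train = nrow(object$train),
              n_val = if (is.null(object$val)) 0L else nrow(object$val),
              label_sd = sd(object$train$label),
              final = h, history = object$history)
  class(out) <- "summary.affinity_model"
  out
}

#' @export
print.summary.affinity_model <- function(x, ...) {
  cat(sprintf("Siamese affinity regressor (encoder '%s', loss %s, %d epochs)\n",
              x$encoder, x$loss, x$epochs))
  cat(sprintf("Training pairs: %d, validation pairs: %d\n", x$n_train, x$n_val))
  cat(sprintf("Training-label SD: %.3f kcal/mol\n", x$label_sd))
  cat(sprintf("Final train %s %.4f (MAE %.4f)", x$loss,
              x$final$train_loss, x$final$train_mae))
  if (!is.na(x$final$val_mae))
    cat(sprintf("; val %s %.4f (MAE %.4f)", x$loss,
                x$final$val_loss, x$final$val_mae))
  cat("\n")
  invisible(x)
}

#' Loss and MAE learning curves
#'
#' @param x an [affinity_model()] fit.
#' @param metric `"loss"` or `"mae"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.affinity_model <- function(x, metric = c("loss", "mae"), ...) {
  metric <- match.arg(metric)
  cols <- if (metric == "loss") c("train_loss", "val_loss")
          else c("train_mae", "val_mae")
  m <- as.matrix(x$history[, cols])
  matplot(x$history$epoch, m, type = "b", pch = c(1, 2), lty = 1,
          col = c("black", "red3"), xlab = "epoch",
          ylab = if (metric == "loss") x$loss else "MAE (kcal/mol)", ...)
  legend("topright", legend = c("train", "validation"), pch = c(1, 2),
         col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' @export
residuals.affinity_model <- function(object, which = c("validation", "train"), ...) {
  which <- match.arg(which)
  d <- if (which == "validation" && !is.null(object$val)) object$val else object$train
  d$label - predict(object, d)
}

#' @export
fitted.affinity_model <- function(object, ...) predict(object, object$train)

#' @export
coef.affinity_model <- function(object, ...) object$head
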