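# Minimal neural-net engine in vectorized base R: an embedding +
# bidirectional LSTM + sigmoid head trained with Adam, and a
# conv-pool-conv-pool-softmax CNN trained with SGD. Written for
# desk-scale batches (hundreds to low thousands of sequences); all
# randomness (init, shuffling, dropout) is driven by the config seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Configuration for the bidirectional LSTM classifier
#'
#' Defaults follow the reference architecture: 64 recurrent units and
#' dropout 0.4 before the dense layer, binary cross-entropy loss and the
#' Adam optimizer, a sigmoid output mapping each sample to a confidence
#' probability. Embedding dimension, epochs, batch size and learning rate
#' have no prescribed values and are exposed here; the `units = 8`-scale
#' configs used in the package's tests are explicit overrides.
#'
#' @param p Word length of the token encoding (default 3); the embedding
#'   vocabulary is `4^p` words plus the padding token 0.
#' @param embed_dim Embedding dimension (default 32).
#' @param units LSTM units per direction (default 64).
#' @param dropout Dropout rate on the concatenated final states (default
#'   0.4).
#' @param epochs,batch_size Training schedule (defaults 10, 64).
#' @param lr Adam learning rate (default 0.002).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(p = 3L, embed_dim = 32L, units = 64L, dropout = 0.4,
                        epochs = 10L, batch_size = 64L, lr = 0.002,
                        seed = 1L) {
  stopifnot(p >= 1L, embed_dim >= 1L, units >= 1L,
            dropout >= 0, dropout < 1, epochs >= 0L, batch_size >= 1L)
  structure(list(p = as.integer(p), vocab_size = 4L^as.integer(p) + 1L,
                 embed_dim = as.integer(embed_dim), units = as.integer(units),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Configuration for the CNN classifier
#'
#' Defaults follow the reference architecture: two convolutional layers
#' with 32 and 64 filters, max-pooling after each, dropout 0.4 before the
#' two-way softmax, categorical cross-entropy loss and the SGD optimizer.
#' Kernel width, pool size, epochs, batch size, learning rate and momentum
#' are exposed knobs.
#'
#' @param filters Filter counts of the two convolutional layers
#'   (default `c(32, 64)`).
#' @param kernel Kernel width along the sequence (default 8; the first
#'   layer spans all 4 one-hot channels).
#' @param pool Max-pool width/stride (default 2).
#' @param dropout Dropout rate before the softmax layer (default 0.4).
#' @param epochs,batch_size Training schedule (defaults 10, 64).
#' @param lr,momentum SGD learning rate and momentum (defaults 0.03, 0.9).
#' @param seed Integer seed.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(filters = c(32L, 64L), kernel = 8L, pool = 2L,
                       dropout = 0.4, epochs = 10L, batch_size = 64L,
                       lr = 0.03, momentum = 0.9, seed = 1L) {
  stopifnot(length(filters) == 2L, all(filters >= 1L), kernel >= 2L,
            pool >= 1L, dropout >= 0, dropout < 1, epochs >= 0L)
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an untrained bidirectional LSTM model
#'
#' Architecture: word embedding (padding token fixed at the zero vector
#' and masked, so padding injects no signal) -> one forward and one
#' backward LSTM pass -> concatenated final states -> dropout -> dense ->
#' sigmoid confidence probability.
#'
#' @param cfg An [lstm_config()].
#' @param vocab_size Optional explicit vocabulary size; must equal
#'   `4^p + 1` for the configured `p`.
#' @return A list of class `hdeep_lstm`.
#' @export
build_lstm <- function(cfg = lstm_config(), vocab_size = NULL) {
  stopifnot(inherits(cfg, "lstm_config"))
  if (!is.null(vocab_size) && vocab_size != cfg$vocab_size) {
    stop("vocab_size must be 4^p + 1 = ", cfg$vocab_size,
         " for p = ", cfg$p)
  }
  H <- cfg$units; d <- cfg$embed_dim; V <- cfg$vocab_size
  params <- with_seed(cfg$seed, {
    E <- glorot(V, d)
    E[1L, ] <- 0 # padding row, kept at zero
    list(E = E,
         Wx_f = glorot(d, 4L * H), Wh_f = glorot(H, 4L * H),
         b_f = forget_bias(H),
         Wx_b = glorot(d, 4L * H), Wh_b = glorot(H, 4L * H),
         b_b = forget_bias(H),
         Wd = glorot(2L * H, 1L), bd = 0)
  })
  structure(list(kind = "lstm", cfg = cfg, params = params,
                 opt = NULL, trained = FALSE, history = numeric(0),
                 input_spec = NULL),
            class = c("hdeep_lstm", "hdeep_model"))
}

# Bias init with the forget gate at 1 (gate order: input, forget,
# candidate, output).
forget_bias <- function(H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1
  b
}

#' Build an untrained CNN model
#'
#' Architecture: one-hot input (samples x positions x 4 channels) ->
#' conv(filters 1) -> ReLU -> max-pool -> conv(filters 2) -> ReLU ->
#' max-pool -> flatten -> dropout -> dense -> two-way softmax over
#' (mRNA, lncRNA).
#'
#' @param cfg A [cnn_config()].
#' @param n Input length (one-hot column count); needed to size the dense
#'   layer. Must be at least `2 * kernel + kernel - 1` so both
#'   convolutions see a full receptive field.
#' @return A list of class `hdeep_cnn`.
#' @export
build_cnn <- function(cfg = cnn_config(), n) {
  stopifnot(inherits(cfg, "cnn_config"))
  k <- cfg$kernel
  t1 <- n - k + 1L
  p1 <- t1 %/% cfg$pool
  t2 <- p1 - k + 1L
  p2 <- t2 %/% cfg$pool
  if (t1 < 1L || t2 < 1L || p2 < 1L) {
    stop("input length ", n, " is below the minimum receptive field; ",
         "need at least n = ", (2L * k - 1L) * cfg$pool + k - 1L)
  }
  f1 <- cfg$filters[1L]; f2 <- cfg$filters[2L]
  params <- with_seed(cfg$seed, {
    list(W1 = array(glorot(k * 4L, f1), c(k, 4L, f1)), b1 = numeric(f1),
         W2 = array(glorot(k * f1, f2), c(k, f1, f2)), b2 = numeric(f2),
         Wd = glorot(p2 * f2, 2L), bd = numeric(2L))
  })
  structure(list(kind = "cnn", cfg = cfg, params = params,
                 opt = NULL, trained = FALSE, history = numeric(0),
                 input_spec = list(n = as.integer(n), t1 = t1, p1 = p1,
                                   t2 = t2, p2 = p2)),
            class = c("hdeep_cnn", "hdeep_model"))
}

## ---- LSTM forward/backward ------------------------------------------------

lstm_pass <- function(tokens, E, Wx, Wh, b, order_t) {
  B <- nrow(tokens); H <- nrow(Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", length(order_t))
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  for (step in seq_along(order_t)) {
    t <- order_t[step]
    idx <- tokens[, t]
    m <- as.numeric(idx > 0L)
    x <- E[idx + 1L, , drop = FALSE]
    z <- x %*% Wx + h %*% Wh + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * g
    tanhc <- tanh(c_new)
    h_new <- o * tanhc
    cache[[step]] <- list(idx = idx, m = m, i = i, f = f, g = g, o = o,
                          c_prev = cc, h_prev = h, tanhc = tanhc)
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
  }
  list(h = h, cache = cache)
}

lstm_pass_backward <- function(dh, cache, tokens, E, Wx, Wh, order_t) {
  B <- nrow(dh); H <- ncol(dh)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4L * H)
  dE <- E * 0
  dc <- matrix(0, B, H)
  for (step in rev(seq_along(order_t))) {
    s <- cache[[step]]
    m <- s$m
    dh_eff <- m * dh
    do <- dh_eff * s$tanhc
    dc_new <- m * dc + dh_eff * s$o * (1 - s$tanhc^2)
    di <- dc_new * s$g
    df <- dc_new * s$c_prev
    dg <- dc_new * s$i
    dzi <- di * s$i * (1 - s$i)
    dzf <- df * s$f * (1 - s$f)
    dzg <- dg * (1 - s$g^2)
    dzo <- do * s$o * (1 - s$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    x <- E[s$idx + 1L, , drop = FALSE]
    dWx <- dWx + crossprod(x, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx <- dz %*% t(Wx)
    live <- which(s$idx > 0L)
    if (length(live)) {
      agg <- rowsum(dx[live, , drop = FALSE], s$idx[live])
      rows <- as.integer(rownames(agg)) + 1L
      dE[rows, ] <- dE[rows, , drop = FALSE] + agg
    }
    dh <- (1 - m) * dh + dz %*% t(Wh)
    dc <- dc_new * s$f + (1 - m) * dc
  }
  list(dWx = dWx, dWh = dWh, db = db, dE = dE)
}

lstm_forward_full <- function(params, tokens, dropout_keep = NULL) {
  T_ <- ncol(tokens)
  fwd <- lstm_pass(tokens, params$E, params$Wx_f, params$Wh_f, params$b_f,
                   seq_len(T_))
  bwd <- lstm_pass(tokens, params$E, params$Wx_b, params$Wh_b, params$b_b,
                   rev(seq_len(T_)))
  concat <- cbind(fwd$h, bwd$h)
  a <- if (is.null(dropout_keep)) concat else concat * dropout_keep
  prob <- sigmoid(drop(a %*% params$Wd) + params$bd)
  list(prob = prob, a = a, fwd = fwd, bwd = bwd)
}

lstm_batch_grads <- function(params, tokens, y, dropout) {
  B <- nrow(tokens); T_ <- ncol(tokens); H <- nrow(params$Wh_f)
  keep <- if (dropout > 0) {
    matrix(stats::rbinom(B * 2L * H, 1L, 1 - dropout), B, 2L * H) /
      (1 - dropout)
  } else NULL
  fw <- lstm_forward_full(params, tokens, dropout_keep = keep)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- matrix((fw$prob - y) / B, ncol = 1L)
  dWd <- crossprod(fw$a, dlogit)
  dbd <- sum(dlogit)
  da <- dlogit %*% t(params$Wd)
  if (!is.null(keep)) da <- da * keep
  gf <- lstm_pass_backward(da[, 1:H, drop = FALSE], fw$fwd$cache, tokens,
                           params$E, params$Wx_f, params$Wh_f, seq_len(T_))
  gb <- lstm_pass_backward(da[, (H + 1L):(2L * H), drop = FALSE],
                           fw$bwd$cache, tokens,
                           params$E, params$Wx_b, params$Wh_b,
                           rev(seq_len(T_)))
  dE <- gf$dE + gb$dE
  dE[1L, ] <- 0 # padding embedding stays zero
  list(loss = loss,
       grads = list(E = dE,
                    Wx_f = gf$dWx, Wh_f = gf$dWh, b_f = gf$db,
                    Wx_b = gb$dWx, Wh_b = gb$dWh, b_b = gb$db,
                    Wd = dWd, bd = dbd))
}

## ---- CNN forward/backward -------------------------------------------------

conv1d_forward <- function(x, W, b) {
  # x: B x T x C; W: k x C x F
  B <- dim(x)[1L]; T_ <- dim(x)[2L]; C <- dim(x)[3L]
  k <- dim(W)[1L]; F_ <- dim(W)[3L]
  To <- T_ - k + 1L
  zmat <- matrix(0, B * To, F_)
  for (w in seq_len(k)) {
    xs <- matrix(x[, w:(w + To - 1L), , drop = FALSE], B * To, C)
    zmat <- zmat + xs %*% matrix(W[w, , ], C, F_)
  }
  zmat <- sweep(zmat, 2L, b, "+")
  array(zmat, c(B, To, F_))
}

conv1d_backward <- function(x, W, dz) {
  B <- dim(x)[1L]; C <- dim(x)[3L]
  k <- dim(W)[1L]; F_ <- dim(W)[3L]
  To <- dim(dz)[2L]
  dzmat <- matrix(dz, B * To, F_)
  dW <- W * 0
  dx <- x * 0
  for (w in seq_len(k)) {
    xs <- matrix(x[, w:(w + To - 1L), , drop = FALSE], B * To, C)
    dW[w, , ] <- crossprod(xs, dzmat)
    dxs <- dzmat %*% t(matrix(W[w, , ], C, F_))
    dx[, w:(w + To - 1L), ] <- dx[, w:(w + To - 1L), , drop = FALSE] +
      array(dxs, c(B, To, C))
  }
  list(dW = dW, db = colSums(dzmat), dx = dx)
}

maxpool_forward <- function(a, pool) {
  B <- dim(a)[1L]; T_ <- dim(a)[2L]; F_ <- dim(a)[3L]
  Tp <- T_ %/% pool
  slices <- lapply(seq_len(pool), function(s) {
    a[, seq.int(s, by = pool, length.out = Tp), , drop = FALSE]
  })
  p <- slices[[1L]]
  argmax <- array(1L, dim(p))
  if (pool > 1L) {
    for (s in 2:pool) {
      better <- slices[[s]] > p
      p[better] <- slices[[s]][better]
      argmax[better] <- s
    }
  }
  list(p = p, argmax = argmax, Tp = Tp)
}

maxpool_backward <- function(dp, argmax, pool, T_) {
  B <- dim(dp)[1L]; Tp <- dim(dp)[2L]; F_ <- dim(dp)[3L]
  da <- array(0, c(B, T_, F_))
  for (s in seq_len(pool)) {
    sel <- (argmax == s) * dp
    da[, seq.int(s, by = pool, length.out = Tp), ] <- sel
  }
  da
}

cnn_forward <- function(model, x, dropout_keep = NULL) {
  p <- model$params; cfg <- model$cfg
  z1 <- conv1d_forward(x, p$W1, p$b1)
  a1 <- pmax(z1, 0)
  pool1 <- maxpool_forward(a1, cfg$pool)
  z2 <- conv1d_forward(pool1$p, p$W2, p$b2)
  a2 <- pmax(z2, 0)
  pool2 <- maxpool_forward(a2, cfg$pool)
  B <- dim(x)[1L]
  flat <- matrix(pool2$p, B)
  a <- if (is.null(dropout_keep)) flat else flat * dropout_keep
  logits <- sweep(a %*% p$Wd, 2L, p$bd, "+")
  logits <- logits - apply(logits, 1L, max)
  expz <- exp(logits)
  probs <- expz / rowSums(expz)
  list(probs = probs, a = a, flat = flat, z1 = z1, a1 = a1, pool1 = pool1,
       z2 = z2, a2 = a2, pool2 = pool2)
}

cnn_batch_grads <- function(model, x, y, dropout) {
  p <- model$params; cfg <- model$cfg
  B <- dim(x)[1L]
  D <- nrow(p$Wd)
  keep <- if (dropout > 0) {
    matrix(stats::rbinom(B * D, 1L, 1 - dropout), B, D) / (1 - dropout)
  } else NULL
  fw <- cnn_forward(model, x, dropout_keep = keep)
  yv <- unname(cbind(1 - y, y)) # columns: mRNA, lncRNA
  pr <- pmin(pmax(fw$probs, 1e-12), 1)
  loss <- -mean(rowSums(yv * log(pr)))
  dlogits <- (fw$probs - yv) / B
  dWd <- crossprod(fw$a, dlogits)
  dbd <- colSums(dlogits)
  dflat <- dlogits %*% t(p$Wd)
  if (!is.null(keep)) dflat <- dflat * keep
  dpool2 <- array(dflat, dim(fw$pool2$p))
  da2 <- maxpool_backward(dpool2, fw$pool2$argmax, cfg$pool, dim(fw$a2)[2L])
  dz2 <- da2 * (fw$z2 > 0)
  g2 <- conv1d_backward(fw$pool1$p, p$W2, dz2)
  da1p <- g2$dx
  da1 <- maxpool_backward(da1p, fw$pool1$argmax, cfg$pool, dim(fw$a1)[2L])
  dz1 <- da1 * (fw$z1 > 0)
  g1 <- conv1d_backward(x, p$W1, dz1)
  list(loss = loss,
       grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    Wd = dWd, bd = dbd))
}

## ---- Optimizers -----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, state, lr, momentum) {
  if (is.null(state)) state <- lapply(params, function(p) p * 0)
  for (nm in names(grads)) {
    state[[nm]] <- momentum * state[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + state[[nm]]
  }
  list(params = params, state = state)
}

## ---- Training and prediction ----------------------------------------------

#' Train a model on encoded sequences
#'
#' Runs minibatch training (Adam + binary cross-entropy for the LSTM,
#' SGD + categorical cross-entropy for the CNN) and records the mean
#' training loss per epoch. Fully deterministic for a fixed config seed
#' in single-threaded BLAS.
#'
#' @param model An untrained or trained model from [build_lstm()] or
#'   [build_cnn()].
#' @param x Encoded inputs: a token matrix (samples x width) for the
#'   LSTM, a one-hot array (samples x positions x 4) for the CNN.
#' @param y Integer labels over {0, 1} (1 = lncRNA).
#' @param verbose Print the per-epoch loss.
#' @return The fitted model, with `history` (loss per epoch) and
#'   `trained = TRUE` when at least one epoch ran.
#' @export
fit_model <- function(model, x, y, verbose = FALSE) {
  UseMethod("fit_model")
}

fit_loop <- function(model, x, y, grad_fun, step_fun, get_batch, verbose) {
  cfg <- model$cfg
  n <- length(y)
  stopifnot(all(y %in% 0:1))
  params <- model$params
  opt <- model$opt
  history <- numeric(0)
  with_seed(cfg$seed + 7L, {
    if (cfg$epochs > 0L) {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- c()
        for (start in seq(1L, n, by = cfg$batch_size)) {
          idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
          g <- grad_fun(params, get_batch(x, idx), y[idx])
          st <- step_fun(params, g$grads, opt)
          params <- st$params
          opt <- st$state
          losses <- c(losses, g$loss)
        }
        history <- c(history, mean(losses))
        if (verbose) {
          message(sprintf("epoch %d/%d  loss %.4f", epoch, cfg$epochs,
                          mean(losses)))
        }
      }
    }
  })
  model$params <- params
  model$opt <- opt
  model$history <- c(model$history, history)
  model$trained <- model$trained || cfg$epochs > 0L
  model
}

#' @export
fit_model.hdeep_lstm <- function(model, x, y, verbose = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (max(x) > model$cfg$vocab_size - 1L || min(x) < 0L) {
    stop("token values outside the model vocabulary 0..",
         model$cfg$vocab_size - 1L)
  }
  model$input_spec <- list(p = model$cfg$p, width = ncol(x))
  state <- if (is.null(model$opt)) adam_init(model$params) else model$opt
  model$opt <- state
  fit_loop(model, x, y,
           grad_fun = function(params, xb, yb) {
             lstm_batch_grads(params, xb, yb, model$cfg$dropout)
           },
           step_fun = function(params, grads, opt) {
             adam_step(params, grads, opt, lr = model$cfg$lr)
           },
           get_batch = function(x, idx) x[idx, , drop = FALSE],
           verbose = verbose)
}

#' @export
fit_model.hdeep_cnn <- function(model, x, y, verbose = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1L] == length(y),
            dim(x)[2L] == model$input_spec$n, dim(x)[3L] == 4L)
  fit_loop(model, x, y,
           grad_fun = function(params, xb, yb) {
             m <- model; m$params <- params
             cnn_batch_grads(m, xb, yb, model$cfg$dropout)
           },
           step_fun = function(params, grads, opt) {
             sgd_step(params, grads, opt, lr = model$cfg$lr,
                      momentum = model$cfg$momentum)
           },
           get_batch = function(x, idx) x[idx, , , drop = FALSE],
           verbose = verbose)
}

#' Confidence probabilities from a trained model
#'
#' Maps each encoded sample to the model's confidence that it is a
#' lncRNA: the sigmoid output for the LSTM, the lncRNA component of the
#' two-way softmax for the CNN (the two components sum to 1).
#'
#' @param model A fitted model; predicting from an untrained model is
#'   allowed but warns.
#' @param x Encoded inputs matching the model kind.
#' @return Numeric vector of confidence probabilities in `[0, 1]`, one
#'   per sample, in input order.
#' @export
predict_cp <- function(model, x) {
  UseMethod("predict_cp")
}

#' @export
predict_cp.hdeep_lstm <- function(model, x) {
  if (!model$trained) warning("predicting from an untrained LSTM model")
  stopifnot(is.matrix(x))
  unname(lstm_forward_full(model$params, x)$prob)
}

#' @export
predict_cp.hdeep_cnn <- function(model, x) {
  if (!model$trained) warning("predicting from an untrained CNN model")
  stopifnot(length(dim(x)) == 3L)
  unname(cnn_forward(model, x)$probs[, 2L])
}

#' @export
print.hdeep_model <- function(x, ...) {
  cat(sprintf("<%s model: %s, %s>\n",
              toupper(x$kind),
              if (x$trained) "trained" else "untrained",
              if (x$kind == "lstm") {
                sprintf("p=%d, %d units, embed %d", x$cfg$p, x$cfg$units,
                        x$cfg$embed_dim)
              } else {
                sprintf("filters %s, kernel %d",
                        paste(x$cfg$filters, collapse = "/"), x$cfg$kernel)
              }))
  if (length(x$history)) {
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                utils::tail(x$history, 1L), length(x$history)))
  }
  invisible(x)
}
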