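tiny_lstm_cfg <- function(epochs = 2L) {
  lstm_config(embed_dim = 4L, units = 3L, dropout = 0, epochs = epochs,
              batch_size = 8L, seed = 2L)
}

tiny_cnn_cfg <- function(epochs = 2L) {
  cnn_config(filters = c(3L, 4L), kernel = 4L, dropout = 0, epochs = epochs,
             batch_size = 8L, seed = 2L)
}

test_that("LSTM vocabulary is 4^p plus the padding token", {
  m <- build_lstm(lstm_config(p = 3L))
  expect_equal(m$cfg$vocab_size, 65L)
  expect_equal(nrow(m$params$E), 65L)
  expect_true(all(m$params$E[1L, ] == 0))
  expect_error(build_lstm(lstm_config(p = 3L), vocab_size = 17L), "4\\^p")
  expect_equal(build_lstm(lstm_config(p = 2L))$cfg$vocab_size, 17L)
})

test_that("default architectures match the reference sizes", {
  expect_equal(lstm_config()$units, 64L)
  expect_equal(lstm_config()$dropout, 0.4)
  expect_equal(cnn_config()$filters, c(32L, 64L))
  expect_equal(cnn_config()$dropout, 0.4)
})

test_that("CNN rejects inputs below its receptive field", {
  expect_error(build_cnn(cnn_config(kernel = 8L), n = 10L), "at least n")
  expect_silent(build_cnn(cnn_config(kernel = 8L), n = 60L))
})

test_that("analytic LSTM gradients match finite differences", {
  cfg <- tiny_lstm_cfg()
  m <- build_lstm(cfg)
  set.seed(9)
  x <- matrix(sample(0:64, 5L * 6L, replace = TRUE), 5L, 6L)
  x[1L, ] <- 0L # an all-padding row must not break gradients
  x[2:5, 5:6] <- 0L
  y <- c(0, 1, 1, 0, 1)
  g <- plncHDeep:::lstm_batch_grads(m$params, x, y, dropout = 0)
  loss_at <- function(params) {
    plncHDeep:::lstm_batch_grads(params, x, y, dropout = 0)$loss
  }
  eps <- 1e-6
  for (nm in c("E", "Wx_f", "Wh_b", "b_f", "Wd", "bd")) {
    p <- m$params[[nm]]
    for (probe in seq_len(min(4L, length(p)))) {
      i <- if (nm == "E") probe + 4L else probe # skip the fixed pad row
      pp <- m$params; pp[[nm]][i] <- p[i] + eps
      pm <- m$params; pm[[nm]][i] <- p[i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("analytic CNN gradients match finite differences", {
  cfg <- tiny_cnn_cfg()
  m <- build_cnn(cfg, n = 20L)
  set.seed(10)
  x <- array(0L, c(4L, 20L, 4L))
  for (i in 1:4) {
    x[i, , ] <- t(encode_onehot(random_seq(sample(15:20, 1L)), n = 20L))
  }
  y <- c(0, 1, 0, 1)
  g <- plncHDeep:::cnn_batch_grads(m, x, y, dropout = 0)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    plncHDeep:::cnn_batch_grads(mm, x, y, dropout = 0)$loss
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in seq_len(min(4L, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- p[i] + eps
      pm <- m$params; pm[[nm]][i] <- p[i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss on separable synthetic data", {
  tr <- toy_transcripts(20L, seed = 21L)
  xt <- encode_pnt_batch(tr, p = 3L)
  lstm <- fit_model(build_lstm(lstm_config(embed_dim = 8L, units = 8L,
                                           epochs = 6L, batch_size = 16L,
                                           seed = 3L)),
                    xt, tr$label)
  expect_length(lstm$history, 6L)
  expect_lt(utils::tail(lstm$history, 1L), lstm$history[1L])

  xo <- encode_onehot_batch(tr)
  cnn <- fit_model(build_cnn(cnn_config(filters = c(4L, 8L), epochs = 6L,
                                        batch_size = 16L, seed = 3L),
                             n = dim(xo)[2L]),
                   xo, tr$label)
  expect_lt(utils::tail(cnn$history, 1L), cnn$history[1L])
})

test_that("training is deterministic for a fixed seed", {
  tr <- toy_transcripts(8L, seed = 22L)
  xt <- encode_pnt_batch(tr, p = 3L)
  cfg <- lstm_config(embed_dim = 4L, units = 4L, epochs = 2L,
                     batch_size = 8L, seed = 5L)
  m1 <- fit_model(build_lstm(cfg), xt, tr$label)
  m2 <- fit_model(build_lstm(cfg), xt, tr$label)
  expect_identical(m1$history, m2$history)
  expect_identical(predict_cp(m1, xt), predict_cp(m2, xt))
})

test_that("prediction contracts: range, order, softmax complement", {
  tr <- toy_transcripts(8L, seed = 23L)
  xt <- encode_pnt_batch(tr, p = 3L)
  xo <- encode_onehot_batch(tr)
  lstm <- fit_model(build_lstm(tiny_lstm_cfg()), xt, tr$label)
  cp <- predict_cp(lstm, xt)
  expect_length(cp, nrow(tr))
  expect_true(all(cp >= 0 & cp <= 1))
  expect_identical(cp[1:3], predict_cp(lstm, xt[1:3, , drop = FALSE]))

  cnn <- fit_model(build_cnn(tiny_cnn_cfg(), n = dim(xo)[2L]), xo, tr$label)
  probs <- plncHDeep:::cnn_forward(cnn, xo)$probs
  expect_equal(rowSums(probs), rep(1, nrow(tr)))
  expect_equal(predict_cp(cnn, xo), unname(probs[, 2L]))

  pad <- matrix(0L, 2L, ncol(xt))
  cp_pad <- predict_cp(lstm, pad)
  expect_true(all(cp_pad >= 0 & cp_pad <= 1))
})

test_that("zero-epoch fits stay untrained and near chance", {
  tr <- toy_transcripts(6L, seed = 24L)
  xt <- encode_pnt_batch(tr, p = 3L)
  m <- fit_model(build_lstm(tiny_lstm_cfg(epochs = 0L)), xt, tr$label)
  expect_false(m$trained)
  expect_warning(cp <- predict_cp(m, xt), "untrained")
  expect_true(all(abs(cp - 0.5) < 0.2))
})
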