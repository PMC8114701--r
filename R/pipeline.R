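#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end run. The `tiny` preset shrinks
#' both networks (8 LSTM units, 8/16 CNN filters, short schedules) to the
#' scale used throughout the package's tests and examples; the
#' `reference` preset keeps the full sizes (64 units, 32/64 filters).
#'
#' @param p Token word length (default 3).
#' @param ratio Negatives per positive after undersampling (1, 2 or 3).
#' @param split_fraction Training fraction of the 80/20 split.
#' @param strategy Hybrid strategy: `"lstm"`, `"cnn"` or `"greedy"`.
#' @param n_clusters Cluster count for undersampling.
#' @param scale `"tiny"` or `"reference"` model sizing.
#' @param lstm,cnn Explicit [lstm_config()] / [cnn_config()] overriding
#'   `scale`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `hdeep_config`.
#' @export
hdeep_config <- function(p = 3L, ratio = 1L, split_fraction = 0.8,
                         strategy = c("lstm", "cnn", "greedy"),
                         n_clusters = 200L,
                         scale = c("tiny", "reference"),
                         lstm = NULL, cnn = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  scale <- match.arg(scale)
  seed <- as.integer(seed)
  if (is.null(lstm)) {
    lstm <- if (scale == "tiny") {
      lstm_config(p = p, embed_dim = 8L, units = 8L, epochs = 12L,
                  batch_size = 64L, seed = seed)
    } else {
      lstm_config(p = p, seed = seed)
    }
  }
  if (is.null(cnn)) {
    cnn <- if (scale == "tiny") {
      cnn_config(filters = c(8L, 16L), epochs = 12L, batch_size = 64L,
                 seed = seed)
    } else {
      cnn_config(seed = seed)
    }
  }
  structure(list(p = as.integer(p), ratio = as.integer(ratio),
                 split_fraction = split_fraction, strategy = strategy,
                 n_clusters = as.integer(n_clusters),
                 lstm = lstm, cnn = cnn, seed = seed),
            class = "hdeep_config")
}

#' End-to-end hybrid classification run
#'
#' Executes the full protocol on labeled positive and negative transcript
#' tables: undersample negatives to the requested ratio, stratified
#' 80/20 split, encode the training set both ways (token vectors and
#' one-hot matrices, widths fixed on the training set), train the BiLSTM
#' and the CNN, predict confidence probabilities on the held-out test
#' set, fuse them with the chosen hybrid strategy, and evaluate.
#'
#' @param pos Positive (lncRNA) transcript table.
#' @param neg Negative (mRNA) transcript table.
#' @param config An [hdeep_config()].
#' @param balance Apply clustering-based undersampling of the negatives
#'   (default `TRUE`; set `FALSE` to use `neg` as is).
#' @return A list of class `hdeep_run`: `predictions` (test-set
#'   `data.frame` with id, truth, cp_l, cp_c, cp, label), `metrics`
#'   (named list with one metric vector per method plus AUCs), `models`,
#'   `split`, `manifest`.
#' @export
run_hdeep <- function(pos, neg, config = hdeep_config(), balance = TRUE) {
  stopifnot(inherits(config, "hdeep_config"))
  seed <- config$seed
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dataset <- stage("balance", {
    if (balance) {
      make_ratio_dataset(pos, neg, ratio = config$ratio,
                         n_clusters = config$n_clusters, seed = seed)
    } else {
      pos$label <- 1L; neg$label <- 0L
      rbind(pos, neg)
    }
  })
  sp <- stage("split", {
    split_dataset(dataset, fraction = config$split_fraction,
                  seed = seed + 1L)
  })
  width <- batch_width(sp$train, config$p)
  n_onehot <- batch_width(sp$train, 1L)
  enc <- stage("encode", {
    list(train_tok = encode_pnt_batch(sp$train, p = config$p, width = width),
         test_tok = suppressWarnings(
           encode_pnt_batch(sp$test, p = config$p, width = width)),
         train_oh = encode_onehot_batch(sp$train, n = n_onehot),
         test_oh = suppressWarnings(encode_onehot_batch(sp$test,
                                                        n = n_onehot)))
  })
  lstm <- stage("train_lstm", {
    fit_model(build_lstm(config$lstm), enc$train_tok, sp$train$label)
  })
  cnn <- stage("train_cnn", {
    fit_model(build_cnn(config$cnn, n = n_onehot), enc$train_oh,
              sp$train$label)
  })
  cp_l <- stage("predict", predict_cp(lstm, enc$test_tok))
  cp_c <- stage("predict", predict_cp(cnn, enc$test_oh))
  fused <- stage("fuse", fuse_cp(cp_l, cp_c, strategy = config$strategy))
  predictions <- data.frame(id = sp$test$id, truth = sp$test$label, fused)
  metrics <- stage("evaluate", {
    truth <- sp$test$label
    list(lstm = classification_metrics(confusion(truth, to_label(cp_l))),
         cnn = classification_metrics(confusion(truth, to_label(cp_c))),
         hybrid = classification_metrics(confusion(truth, fused$label)),
         auc = c(lstm = roc_auc(cp_l, truth)$auc,
                 cnn = roc_auc(cp_c, truth)$auc,
                 hybrid = roc_auc(fused$cp, truth)$auc))
  })
  manifest <- list(
    command = "run_hdeep",
    version = as.character(utils::packageVersion("plncHDeep")),
    seed = seed,
    config = list(p = config$p, ratio = config$ratio,
                  split_fraction = config$split_fraction,
                  strategy = config$strategy,
                  n_clusters = config$n_clusters,
                  lstm = unclass(config$lstm), cnn = unclass(config$cnn)),
    counts = list(n_pos_in = nrow(pos), n_neg_in = nrow(neg),
                  n_dataset = nrow(dataset),
                  n_train = nrow(sp$train), n_test = nrow(sp$test)),
    widths = list(token_width = width, onehot_n = n_onehot),
    timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(predictions = predictions, metrics = metrics,
                 models = list(lstm = lstm, cnn = cnn), split = sp,
                 manifest = manifest),
            class = "hdeep_run")
}

#' @export
print.hdeep_run <- function(x, ...) {
  cat("<hybrid run>\n")
  for (m in c("lstm", "cnn", "hybrid")) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-6s acc %.3f  f1 %.3f  auc %.4f\n", m,
                v[["accuracy"]], v[["f1"]], x$metrics$auc[[m]]))
  }
  invisible(x)
}

#' Balanced-vs-imbalanced ratio experiment
#'
#' Repeats the full run at positive:negative ratios 1:1, 1:2, 1:3 (or any
#' subset) and reports the hybrid model's F1, AUC and GM per ratio; GM is
#' included because it stays informative when the test set is imbalanced.
#'
#' @param pos,neg Transcript tables as in [run_hdeep()].
#' @param ratios Integer vector of negative multiples (default `1:3`).
#' @param config An [hdeep_config()]; its `ratio` field is overridden.
#' @return A `data.frame` with columns `ratio`, `f1`, `auc`, `gm`,
#'   `accuracy`, and attribute `runs` holding the full run objects.
#' @export
ratio_experiment <- function(pos, neg, ratios = 1:3,
                             config = hdeep_config()) {
  runs <- lapply(ratios, function(r) {
    cfg <- config
    cfg$ratio <- as.integer(r)
    run_hdeep(pos, neg, cfg)
  })
  out <- data.frame(
    ratio = ratios,
    f1 = vapply(runs, function(x) x$metrics$hybrid[["f1"]], numeric(1)),
    auc = vapply(runs, function(x) x$metrics$auc[["hybrid"]], numeric(1)),
    gm = vapply(runs, function(x) x$metrics$hybrid[["gm"]], numeric(1)),
    accuracy = vapply(runs, function(x) x$metrics$hybrid[["accuracy"]],
                      numeric(1)))
  attr(out, "runs") <- runs
  out
}

#' Write a run manifest as JSON
#'
#' @param run An `hdeep_run` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
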