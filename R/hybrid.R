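check_cp <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("'", what, "' must be confidence probabilities in [0, 1]")
  }
}

#' Greedy hybrid strategy
#'
#' Selects, per sample, the more decisive of the two confidence
#' probabilities, decisiveness being the distance from the 0.5 fence
#' measured as `|2 Cp - 1|`: the CNN value is kept when
#' `|2 Cp_L - 1| <= |2 Cp_C - 1|` (ties go to the CNN), otherwise the
#' LSTM value. Note a confident rejection (Cp near 0) is as decisive as a
#' confident acceptance.
#'
#' @param cp_l,cp_c Numeric vectors of confidence probabilities in
#'   `[0, 1]` from the LSTM and the CNN (recycled to a common length).
#' @return Fused confidence probabilities (always one of the two inputs).
#' @export
fuse_greedy <- function(cp_l, cp_c) {
  check_cp(cp_l, "cp_l"); check_cp(cp_c, "cp_c")
  ifelse(abs(2 * cp_l - 1) <= abs(2 * cp_c - 1), cp_c, cp_l)
}

#' CNN-dominant hybrid strategy
#'
#' Trusts the CNN unless it is indecisive: the LSTM value is used when
#' `|2 Cp_C - 1| <= 0.5` (i.e. Cp_C in [0.25, 0.75]), otherwise the CNN
#' value.
#'
#' @inheritParams fuse_greedy
#' @return Fused confidence probabilities.
#' @export
fuse_cnn_dominant <- function(cp_l, cp_c) {
  check_cp(cp_l, "cp_l"); check_cp(cp_c, "cp_c")
  ifelse(abs(2 * cp_c - 1) <= 0.5, cp_l, cp_c)
}

#' LSTM-dominant hybrid strategy
#'
#' The mirror of [fuse_cnn_dominant()], and the default strategy of the
#' hybrid classifier: the CNN value is used when `|2 Cp_L - 1| <= 0.5`,
#' otherwise the LSTM value.
#'
#' @inheritParams fuse_greedy
#' @return Fused confidence probabilities.
#' @export
fuse_lstm_dominant <- function(cp_l, cp_c) {
  check_cp(cp_l, "cp_l"); check_cp(cp_c, "cp_c")
  ifelse(abs(2 * cp_l - 1) <= 0.5, cp_c, cp_l)
}

#' Fuse confidence probabilities by a named strategy
#'
#' @inheritParams fuse_greedy
#' @param strategy `"lstm"` (LSTM-dominant, the default), `"cnn"`
#'   (CNN-dominant) or `"greedy"`.
#' @return A `data.frame` with columns `cp_l`, `cp_c`, `cp`, `label`.
#' @export
fuse_cp <- function(cp_l, cp_c, strategy = c("lstm", "cnn", "greedy")) {
  strategy <- match.arg(strategy)
  cp <- switch(strategy,
               lstm = fuse_lstm_dominant(cp_l, cp_c),
               cnn = fuse_cnn_dominant(cp_l, cp_c),
               greedy = fuse_greedy(cp_l, cp_c))
  data.frame(cp_l = cp_l, cp_c = cp_c, cp = cp, label = to_label(cp))
}

#' Map confidence probabilities to class labels
#'
#' @param cp Confidence probabilities in `[0, 1]`.
#' @return Integer labels: 1 (lncRNA) when `cp >= 0.5`, else 0 (mRNA).
#' @export
to_label <- function(cp) {
  check_cp(cp, "cp")
  as.integer(cp >= 0.5)
}
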