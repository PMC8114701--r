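# Digit values for the token map; same base order as the one-hot rows.
BASE_DIGIT <- c(A = 0L, T = 1L, C = 2L, G = 3L)

#' p-nucleotide token encoding of one sequence
#'
#' A window of length `p` slides along the sequence with step `p`
#' (non-overlapping words). Each complete word is mapped to a unique
#' integer in `1..4^p` via the lexicographic order with digit values
#' A=0, T=1, C=2, G=3 (so `AAA -> 1` and `GGG -> 64` for `p = 3`);
#' 0 is reserved for padding. A trailing partial word (`L %% p != 0`) is
#' discarded. The token vector is zero-padded at the end to `width`.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param p Word length (default 3, the best-performing value).
#' @param width Padded length; default is the sequence's own word count
#'   `floor(L / p)`. Must be at least the word count unless
#'   `truncate = TRUE`, in which case longer sequences are cut to `width`
#'   words with a warning.
#' @param truncate Allow cutting sequences longer than `width` words.
#' @return Integer vector of length `width`; values in `0:(4^p)` with 0
#'   only in the trailing padding.
#' @examples
#' encode_pnt("ATCGGA", p = 3) # 7, 61
#' @export
encode_pnt <- function(seq, p = 3L, width = NULL, truncate = FALSE) {
  stopifnot(p >= 1L)
  L <- nchar(seq)
  n_words <- L %/% p
  if (is.null(width)) width <- n_words
  if (n_words > width) {
    if (!truncate) {
      stop("sequence has ", n_words, " words but width is ", width,
           "; use truncate = TRUE to cut")
    }
    warning("truncating sequence from ", n_words, " to ", width, " words")
    n_words <- width
  }
  digits <- BASE_DIGIT[strsplit(substr(seq, 1L, n_words * p), "")[[1]]]
  if (n_words == 0L) return(integer(width))
  m <- matrix(digits, nrow = p)
  tokens <- as.integer(1L + colSums(m * 4^((p - 1L):0)))
  c(tokens, integer(width - n_words))
}

#' One-hot encoding of one sequence
#'
#' Encodes a sequence as a 4-row binary matrix with row order (A, T, C, G):
#' A -> (1,0,0,0), T -> (0,1,0,0), C -> (0,0,1,0), G -> (0,0,0,1), one
#' column per base. Sequences shorter than `n` get all-zero trailing
#' padding columns; longer ones are truncated to the first `n` bases with
#' a warning.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param n Column count (default the sequence length).
#' @return A 4 x `n` integer matrix with rownames A/T/C/G.
#' @export
encode_onehot <- function(seq, n = nchar(seq)) {
  stopifnot(n >= 1L)
  L <- nchar(seq)
  if (L > n) {
    warning("truncating sequence from ", L, " to ", n, " columns")
    seq <- substr(seq, 1L, n)
    L <- n
  }
  idx <- BASE_DIGIT[strsplit(seq, "")[[1]]] + 1L
  m <- matrix(0L, nrow = 4L, ncol = n, dimnames = list(names(BASE_DIGIT), NULL))
  m[cbind(idx, seq_len(L))] <- 1L
  m
}

#' Batch width for an encoding
#'
#' The uniform encoded length is set by the longest sequence in the
#' (training) batch: `floor(max(L) / p)` tokens for the p-nucleotide
#' encoding, or `max(L)` columns for the one-hot encoding (`p = 1`).
#'
#' @param tr Transcript `data.frame` (training set).
#' @param p Word length; use 1 for the one-hot column count.
#' @return Integer width.
#' @export
batch_width <- function(tr, p = 3L) {
  if (nrow(tr) == 0L) stop("empty transcript set")
  max(tr$length) %/% p
}

#' Encode a transcript table as a token matrix
#'
#' @param tr Transcript `data.frame`.
#' @param p Word length.
#' @param width Uniform token count; computed from `tr` via
#'   [batch_width()] when `NULL`. Sequences exceeding it are truncated
#'   with a warning (test-time sequences longer than the training maximum).
#' @return Integer matrix, one row per transcript, `width` columns.
#' @export
encode_pnt_batch <- function(tr, p = 3L, width = NULL) {
  if (is.null(width)) width <- batch_width(tr, p)
  t(vapply(tr$seq, encode_pnt, integer(width),
           p = p, width = width, truncate = TRUE))
}

#' Encode a transcript table as a one-hot array
#'
#' @param tr Transcript `data.frame`.
#' @param n Uniform column count; the batch maximum length when `NULL`.
#' @return Integer array of dim `c(nrow(tr), n, 4)` (sample, position,
#'   channel), channel order A/T/C/G.
#' @export
encode_onehot_batch <- function(tr, n = NULL) {
  if (is.null(n)) n <- batch_width(tr, 1L)
  out <- array(0L, dim = c(nrow(tr), n, 4L))
  for (i in seq_len(nrow(tr))) {
    out[i, , ] <- t(encode_onehot(tr$seq[i], n))
  }
  out
}

# Invert a token vector back to the sequence (padding dropped); the token
# map is a bijection on complete words, used as a test oracle.
decode_pnt <- function(tokens, p = 3L) {
  tokens <- tokens[tokens != 0L]
  if (length(tokens) == 0L) return("")
  words <- vapply(tokens, function(tok) {
    v <- tok - 1L
    d <- integer(p)
    for (i in p:1) {
      d[i] <- v %% 4L
      v <- v %/% 4L
    }
    paste(names(BASE_DIGIT)[d + 1L], collapse = "")
  }, character(1))
  paste(words, collapse = "")
}
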