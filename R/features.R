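BASES <- c("A", "T", "C", "G")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# All k-mer forms for one k, lexicographic with base order A < T < C < G.
kmer_forms <- function(k) {
  grids <- rev(rep(list(BASES), k))
  m <- do.call(expand.grid, c(grids, list(stringsAsFactors = FALSE)))
  apply(m[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' Weighted k-mer frequency features
#'
#' Slides a window of length k (step 1) along the sequence for each
#' `k = 1, ..., k_max` and returns the scaled frequencies
#' `f_j = a_k * c_j / s_k` with `s_k = L - k + 1` matches and the
#' equalizing weight `a_k = 1 / 4^(k_max - k)`, so each k contributes on a
#' comparable scale. Form order is lexicographic with base order
#' A < T < C < G within each k, k ascending; for `k_max = 3` this yields
#' the 4 + 16 + 64 = 84 components of the classical feature vector.
#'
#' @param seq A single nucleotide string over A/C/G/T, length >= `k_max`.
#' @param ks Integer vector of word sizes (default `1:3`).
#' @param k_max Word size used in the weight `a_k`; defaults to `max(ks)`
#'   when all three are used, but is fixed at 3 for the classical features
#'   so that the 1-mer/2-mer subset used for clustering keeps the same
#'   scale.
#' @return Named numeric vector, one component per k-mer form.
#' @examples
#' kmer_freq("AAAA")[c("A", "AA", "AAA")] # 0.0625, 0.25, 1
#' @export
kmer_freq <- function(seq, ks = 1:3, k_max = 3L) {
  stopifnot(length(seq) == 1L)
  L <- nchar(seq)
  if (L < max(ks)) stop("sequence shorter than the largest k (", max(ks), ")")
  dna <- Biostrings::DNAString(seq)
  unlist(lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    forms <- kmer_forms(k)
    c_j <- as.numeric(counts[forms])
    s_k <- L - k + 1
    a_k <- 1 / 4^(k_max - k)
    f <- a_k * c_j / s_k
    names(f) <- forms
    f
  }))
}

#' Find open reading frames in the three forward frames
#'
#' Scans each forward frame left to right; within a frame, the first ATG
#' after the previous ORF's stop opens an ORF that runs to the next
#' in-frame stop codon (TAA/TAG/TGA) inclusive, so reported ORFs are
#' "integrated" (both start and stop present), non-overlapping within a
#' frame, and of length divisible by 3. ORFs shorter than `min_codons`
#' codons (start and stop included) are discarded.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param min_codons Minimum ORF length in codons; default 30 (90 nt), a
#'   conventional floor below which random ORFs are abundant in noncoding
#'   sequence.
#' @return A `data.frame` with columns `start` (1-based), `end` (1-based,
#'   inclusive), `frame` (0/1/2), `length` (nt, stop included); zero rows
#'   when no ORF qualifies.
#' @export
find_orfs <- function(seq, min_codons = 30L) {
  L <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    i <- 1L
    while (i <= n_codons) {
      atg <- which(is_start[i:n_codons])
      if (length(atg) == 0L) break
      a <- i + atg[1L] - 1L
      stp <- which(is_stop[a:n_codons])
      if (length(stp) == 0L) break
      s <- a + stp[1L] - 1L
      len_codons <- s - a + 1L
      if (len_codons >= min_codons) {
        out[[length(out) + 1L]] <-
          c(start = starts[a], end = starts[s] + 2L, frame = frame,
            length = 3L * len_codons)
      }
      i <- s + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

#' ORF-derived features: integrity, coverage, normalized count
#'
#' @param seq Nucleotide string (used for its length `L`).
#' @param orfs ORF table from [find_orfs()] on the same sequence.
#' @return Named numeric vector `c(orf_int, orf_cov, orf_norm)`:
#'   `orf_int` is 1 when at least one integrated ORF exists, else 0;
#'   `orf_cov = sum(l_m) / L`; `orf_norm = n / L`.
#' @export
orf_features <- function(seq, orfs = find_orfs(seq)) {
  L <- nchar(seq)
  n <- nrow(orfs)
  c(orf_int = as.numeric(n >= 1L),
    orf_cov = if (n) sum(orfs$length) / L else 0,
    orf_norm = n / L)
}

# Nussinov-style DP over the folding score count*SCALE + energy, where
# energy is 3 per GC, 2 per AU, 1 per GU pair: pair count is maximized
# first, energy breaks ties. Minimum hairpin loop of 3 unpaired bases.
PAIR_SCALE <- 1000L

pair_energy_matrix <- local({
  m <- matrix(0L, 4L, 4L, dimnames = list(BASES, BASES))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "T"] <- m["T", "A"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
})

nussinov_score <- function(seq) {
  L <- nchar(seq)
  b <- match(strsplit(seq, "")[[1]], BASES)
  pe <- pair_energy_matrix
  M <- matrix(0, L, L)
  if (L >= 5L) {
    for (span in 4L:(L - 1L)) {
      for (i in seq_len(L - span)) {
        j <- i + span
        best <- M[i, j - 1L] # j unpaired
        # j paired with some k in [i, j-4]; recursion covers bifurcation
        ks <- i:(j - 4L)
        e <- pe[cbind(b[ks], rep.int(b[j], length(ks)))]
        pairable <- which(e > 0L)
        if (length(pairable)) {
          kp <- ks[pairable]
          left <- numeric(length(kp))
          left[kp > i] <- M[i, kp[kp > i] - 1L]
          inner <- M[cbind(kp + 1L, rep.int(j - 1L, length(kp)))]
          best <- max(best, PAIR_SCALE + e[pairable] + left + inner)
        }
        M[i, j] <- best
      }
    }
  }
  M[1L, L]
}

#' Secondary-structure features: base pairs, GC content, normalized energy
#'
#' `gc` is `(NG + NC) / (NA + NT + NC + NG)`. The pairing engine predicts a
#' pseudoknot-free secondary structure by a Nussinov dynamic program
#' allowing Watson-Crick (GC, AT/AU) and GU wobble pairs with a minimum
#' hairpin loop of 3 unpaired bases; it maximizes the number of pairs and
#' breaks ties by the per-pair stability proxy 3 (GC), 2 (AU), 1 (GU).
#' `mfe` is minus the optimal proxy score (so more negative means more
#' paired/stable) and `nmfe = mfe / L`. Absolute values are on the proxy
#' scale, not kcal/mol; an external thermodynamic folder can be swapped in
#' via `engine = "external"` by supplying `fold_fun`.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param engine `"internal"` (default) or `"external"`.
#' @param fold_fun For `engine = "external"`: a `function(seq)` returning
#'   `list(n_pairs =, mfe =)` parsed from a folding tool's output.
#' @return Named numeric vector `c(n_pairs, gc, nmfe)`.
#' @export
structure_features <- function(seq, engine = c("internal", "external"),
                               fold_fun = NULL) {
  engine <- match.arg(engine)
  counts <- table(factor(strsplit(seq, "")[[1]], levels = BASES))
  gc <- as.numeric((counts["G"] + counts["C"]) / sum(counts))
  if (engine == "external") {
    if (is.null(fold_fun)) {
      stop("external folding engine not configured; ",
           "pass 'fold_fun' or use engine = \"internal\"")
    }
    res <- fold_fun(seq)
    n_pairs <- res$n_pairs
    mfe <- res$mfe
  } else {
    sc <- nussinov_score(seq)
    n_pairs <- sc %/% PAIR_SCALE
    mfe <- -(sc %% PAIR_SCALE)
  }
  c(n_pairs = as.numeric(n_pairs), gc = gc, nmfe = mfe / nchar(seq))
}

#' Full 90-dimensional classical feature vector
#'
#' Concatenates, in fixed order: the 84 weighted k-mer frequencies
#' (k = 1, 2, 3), the 3 ORF features (`orf_int`, `orf_cov`, `orf_norm`)
#' and the 3 structure features (`n_pairs`, `gc`, `nmfe`).
#'
#' @param seq Nucleotide string over A/C/G/T, length >= 6.
#' @param min_codons Passed to [find_orfs()].
#' @param engine,fold_fun Passed to [structure_features()].
#' @return Named numeric vector of length 90.
#' @export
feature_vector <- function(seq, min_codons = 30L,
                           engine = "internal", fold_fun = NULL) {
  if (nchar(seq) < 6L) stop("sequence too short for feature extraction")
  c(kmer_freq(seq),
    orf_features(seq, find_orfs(seq, min_codons = min_codons)),
    structure_features(seq, engine = engine, fold_fun = fold_fun))
}

#' Feature matrix for a transcript table
#'
#' @param tr Transcript `data.frame`.
#' @param ... Passed to [feature_vector()].
#' @return Numeric matrix, one row per transcript, 90 named columns.
#' @export
feature_matrix <- function(tr, ...) {
  m <- t(vapply(tr$seq, feature_vector, numeric(90L), ...))
  rownames(m) <- tr$id
  m
}
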