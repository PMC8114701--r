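# Positional base preferences inside coding codons (codon positions
# 1, 2, 3), used to give mRNA-like sequences a 3-periodic composition.
CODON_POS_PROFILE <- matrix(
  c(0.35, 0.10, 0.15, 0.40,
    0.35, 0.15, 0.30, 0.20,
    0.10, 0.15, 0.40, 0.35),
  nrow = 3L, byrow = TRUE,
  dimnames = list(NULL, c("A", "T", "C", "G")))

ALL_CODONS <- kmer_forms(3L)
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Configuration for the synthetic transcript generator
#'
#' Bundles the knobs controlling how separable the two synthetic classes
#' are. The defaults are the package's reference test conditions: 400
#' sequences per class, lengths 210-400 nt, mRNA-like ORF coverage 0.9,
#' GC offset 0.1 between classes and codon-bias strength 0.9 (the
#' `"strong"` preset).
#'
#' @param n_pos,n_neg Number of lncRNA-like (positive) and mRNA-like
#'   (negative) sequences.
#' @param len_range Length range in nt, `c(min, max)`; the minimum must be
#'   at least 201 for the lncRNA-like class (lncRNAs are by definition
#'   longer than 200 nt).
#' @param orf_frac_mrna Target fraction of each mRNA-like sequence covered
#'   by its single embedded ORF, in (0, 1].
#' @param gc_shift GC-content offset between the classes: mRNA-like
#'   background GC is `0.5 + gc_shift/2`, lncRNA-like `0.5 - gc_shift/2`.
#' @param periodicity_strength Codon-bias strength in `[0, 1]`. At 0 the
#'   generator is the exact null: both classes are i.i.d. background and
#'   no ORF is embedded. For any value > 0 each mRNA-like sequence carries
#'   one full ATG-to-stop ORF whose interior codons are sense codons drawn
#'   from a mixture `(1 - s) * background + s * periodic profile`.
#' @param effect Convenience preset overriding `gc_shift` and
#'   `periodicity_strength`: `"strong"` (0.1, 0.9), `"weak"` (0.05, 0.4),
#'   `"none"` (0, 0), or `"custom"` (use the explicit values; default).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 400L, n_neg = 400L,
                         len_range = c(210L, 400L),
                         orf_frac_mrna = 0.9,
                         gc_shift = 0.1,
                         periodicity_strength = 0.9,
                         effect = c("custom", "strong", "weak", "none"),
                         seed = 1L) {
  effect <- match.arg(effect)
  preset <- switch(effect,
                   strong = c(0.1, 0.9),
                   weak = c(0.05, 0.4),
                   none = c(0, 0),
                   custom = c(gc_shift, periodicity_strength))
  gc_shift <- preset[1]
  periodicity_strength <- preset[2]
  stopifnot(length(len_range) == 2L, len_range[1] <= len_range[2],
            len_range[1] >= 1L,
            orf_frac_mrna > 0, orf_frac_mrna <= 1,
            gc_shift >= 0, gc_shift <= 1,
            periodicity_strength >= 0, periodicity_strength <= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 len_range = as.integer(len_range),
                 orf_frac_mrna = orf_frac_mrna, gc_shift = gc_shift,
                 periodicity_strength = periodicity_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, T = (1 - gc) / 2, C = gc / 2, G = gc / 2)
}

# Probability of each codon under an i.i.d. base model.
codon_probs_iid <- function(p_base, codons = ALL_CODONS) {
  pr <- vapply(strsplit(codons, ""), function(b) prod(p_base[b]), numeric(1))
  pr / sum(pr)
}

# Positional-profile codon probabilities (sense codons only).
codon_probs_periodic <- function(codons = SENSE_CODONS) {
  pr <- vapply(strsplit(codons, ""), function(b) {
    CODON_POS_PROFILE[1L, b[1]] * CODON_POS_PROFILE[2L, b[2]] *
      CODON_POS_PROFILE[3L, b[3]]
  }, numeric(1))
  pr / sum(pr)
}

rand_bases <- function(n, p_base) {
  sample(names(p_base), n, replace = TRUE, prob = p_base)
}

#' Generate mRNA-like (negative class) sequences
#'
#' Each sequence has i.i.d. background composition with GC content
#' `0.5 + gc_shift/2`, and (for `periodicity_strength > 0`) one embedded
#' open reading frame: an ATG, interior sense codons drawn from the
#' background/periodic codon mixture, and a terminal stop codon, covering
#' about `orf_frac_mrna` of the length at a random in-frame position.
#' At `periodicity_strength = 0` the class is pure background (the null
#' model; no ORF is forced), so that with `gc_shift = 0` the two classes
#' are statistically identical.
#'
#' @param cfg A [synth_config()].
#' @return Transcript `data.frame` with `label = 0`.
#' @export
gen_mrna_like <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  s <- cfg$periodicity_strength
  p_base <- base_probs(0.5 + cfg$gc_shift / 2)
  if (s > 0) {
    q <- (1 - s) * codon_probs_iid(p_base, SENSE_CODONS) +
      s * codon_probs_periodic()
    min_orf <- 9L
    if (cfg$len_range[1] * cfg$orf_frac_mrna < min_orf) {
      stop("sequences too short to host the requested ORF")
    }
  }
  seqs <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_neg), function(i) {
      L <- cfg$len_range[1] +
        sample.int(cfg$len_range[2] - cfg$len_range[1] + 1L, 1L) - 1L
      if (s == 0) return(paste(rand_bases(L, p_base), collapse = ""))
      orf_nt <- max(9L, 3L * round(cfg$orf_frac_mrna * L / 3))
      orf_nt <- min(orf_nt, 3L * (L %/% 3L))
      n_interior <- orf_nt %/% 3L - 2L
      orf <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_interior, replace = TRUE,
                                 prob = q), collapse = ""),
                    sample(STOP_CODONS, 1L))
      start <- sample.int(L - orf_nt + 1L, 1L)
      left <- if (start > 1L) {
        paste(rand_bases(start - 1L, p_base), collapse = "")
      } else ""
      n_right <- L - (start - 1L) - orf_nt
      right <- if (n_right > 0L) {
        paste(rand_bases(n_right, p_base), collapse = "")
      } else ""
      paste0(left, orf, right)
    }, character(1))
  })
  transcripts(id = paste0("mrna_", seq_len(cfg$n_neg)), seq = seqs, label = 0L)
}

#' Generate lncRNA-like (positive class) sequences
#'
#' Pure i.i.d. background sequences of at least 201 nt with GC content
#' `0.5 - gc_shift/2`; no ORF is embedded, so any open reading frames are
#' the short chance ORFs expected in random sequence.
#'
#' @param cfg A [synth_config()].
#' @return Transcript `data.frame` with `label = 1`.
#' @export
gen_lncrna_like <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$len_range[1] < 201L) {
    stop("lncRNA-like sequences must be at least 201 nt; raise len_range")
  }
  p_base <- base_probs(0.5 - cfg$gc_shift / 2)
  seqs <- with_seed(cfg$seed + 1L, {
    vapply(seq_len(cfg$n_pos), function(i) {
      L <- cfg$len_range[1] +
        sample.int(cfg$len_range[2] - cfg$len_range[1] + 1L, 1L) - 1L
      paste(rand_bases(L, p_base), collapse = "")
    }, character(1))
  })
  transcripts(id = paste0("lnc_", seq_len(cfg$n_pos)), seq = seqs, label = 1L)
}

#' Generate a full labeled synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @return Transcript `data.frame`: `n_pos` lncRNA-like rows (label 1)
#'   followed by `n_neg` mRNA-like rows (label 0).
#' @export
gen_dataset <- function(cfg = synth_config()) {
  rbind(gen_lncrna_like(cfg), gen_mrna_like(cfg))
}
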