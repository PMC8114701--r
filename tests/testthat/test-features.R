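# Brute-force k-mer oracle: dictionary counting with substring loops.
kmer_oracle <- function(seq, k_max = 3L) {
  L <- nchar(seq)
  unlist(lapply(seq_len(k_max), function(k) {
    forms <- plncHDeep:::kmer_forms(k)
    counts <- setNames(numeric(length(forms)), forms)
    for (i in seq_len(L - k + 1L)) {
      w <- substr(seq, i, i + k - 1L)
      counts[w] <- counts[w] + 1
    }
    (1 / 4^(k_max - k)) * counts / (L - k + 1L)
  }))
}

test_that("k-mer frequencies match the hand-derived toy values", {
  f <- kmer_freq("AAAA")
  expect_equal(f[["A"]], 0.0625)
  expect_equal(f[["AA"]], 0.25)
  expect_equal(f[["AAA"]], 1)
  expect_length(f, 84L)
  expect_error(kmer_freq("AT"), "shorter")
})

test_that("one-mer components always sum to the weight a_1 = 1/16", {
  set.seed(5)
  for (rep in 1:20) {
    f <- kmer_freq(random_seq(sample(10:200, 1L)))
    expect_equal(sum(f[1:4]), 1 / 16)
  }
})

test_that("k-mer frequencies agree exactly with a dictionary-count oracle", {
  set.seed(19)
  for (rep in 1:300) {
    s <- random_seq(sample(10:80, 1L))
    expect_equal(kmer_freq(s), kmer_oracle(s))
  }
})

# Independent ORF oracle: per frame, a plain state machine over codons.
orf_oracle <- function(seq, min_codons) {
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (frame in 0:2) {
    pos <- frame + 1L
    open_at <- NA_integer_
    while (pos + 2L <= nchar(seq)) {
      codon <- substr(seq, pos, pos + 2L)
      if (is.na(open_at) && codon == "ATG") open_at <- pos
      if (!is.na(open_at) && codon %in% stops) {
        len <- pos + 3L - open_at
        if (len / 3L >= min_codons) {
          hits[[length(hits) + 1L]] <-
            c(start = open_at, end = pos + 2L, frame = frame, length = len)
        }
        open_at <- NA_integer_
      }
      pos <- pos + 3L
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

test_that("ORF finder matches hand scans on the toy cases", {
  o <- find_orfs("ATGAAATAA", min_codons = 3L)
  expect_equal(nrow(o), 1L)
  expect_equal(o$length, 9L)
  expect_equal(o$frame, 0L)
  expect_equal(nrow(find_orfs("CCCCCC", min_codons = 1L)), 0L)
  two <- find_orfs("ATGTAAATGTAA", min_codons = 2L)
  expect_equal(two$length[two$frame == 0L], c(6L, 6L))
  expect_equal(two$start[two$frame == 0L], c(1L, 7L))
})

test_that("ORF finder agrees with an enumerate-and-filter oracle", {
  set.seed(23)
  for (rep in 1:100) {
    s <- random_seq(sample(30:300, 1L))
    got <- find_orfs(s, min_codons = 2L)
    want <- orf_oracle(s, min_codons = 2L)
    ord <- order(got$frame, got$start)
    expect_equal(got[ord, ], want[order(want$frame, want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("ORF features reproduce the coverage arithmetic", {
  seq100 <- strrep("C", 100L)
  one <- data.frame(start = 1L, end = 30L, frame = 0L, length = 30L)
  expect_equal(orf_features(seq100, one),
               c(orf_int = 1, orf_cov = 0.3, orf_norm = 0.01))
  expect_equal(orf_features(seq100, find_orfs(seq100)),
               c(orf_int = 0, orf_cov = 0, orf_norm = 0))
  two <- data.frame(start = c(1L, 40L), end = c(30L, 99L), frame = c(0L, 0L),
                    length = c(30L, 60L))
  expect_equal(orf_features(seq100, two)[["orf_cov"]], 0.9)
})

# Exhaustive enumeration of non-crossing structures (pairs AU/GC/GU,
# hairpin loop >= 3), maximizing pairs then the energy proxy.
enum_best <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  energy <- function(x, y) {
    key <- paste0(sort(c(x, y)), collapse = "")
    switch(key, CG = 3, AT = 2, GT = 1, 0)
  }
  best <- function(i, j) {
    if (j - i < 4L) return(c(0, 0))
    # option: i unpaired
    top <- best(i + 1L, j)
    for (k in (i + 4L):j) {
      e <- energy(b[i], b[k])
      if (e > 0) {
        inner <- best(i + 1L, k - 1L)
        rest <- if (k < j) best(k + 1L, j) else c(0, 0)
        cand <- c(1 + inner[1L] + rest[1L], e + inner[2L] + rest[2L])
        if (cand[1L] > top[1L] ||
            (cand[1L] == top[1L] && cand[2L] > top[2L])) {
          top <- cand
        }
      }
    }
    top
  }
  best(1L, length(b))
}

test_that("pairing engine matches the hand-enumerated toy structures", {
  expect_equal(structure_features("GGGAAACCC"),
               c(n_pairs = 3, gc = 2 / 3, nmfe = -1))
  expect_equal(structure_features("AAAA"),
               c(n_pairs = 0, gc = 0, nmfe = 0))
  expect_equal(structure_features("ATCG")[["gc"]], 0.5)
})

test_that("pairing engine equals exhaustive enumeration up to 12 nt", {
  set.seed(29)
  for (rep in 1:40) {
    s <- random_seq(sample(5:12, 1L))
    want <- enum_best(s)
    got <- structure_features(s)
    expect_equal(got[["n_pairs"]], want[1L], info = s)
    expect_equal(-got[["nmfe"]] * nchar(s), want[2L], info = s)
  }
})

test_that("gc and AT fractions are complementary", {
  set.seed(37)
  for (rep in 1:20) {
    s <- random_seq(sample(5:100, 1L))
    counts <- table(factor(strsplit(s, "")[[1]],
                           levels = c("A", "T", "C", "G")))
    at <- (counts[["A"]] + counts[["T"]]) / nchar(s)
    expect_equal(structure_features(s)[["gc"]] + at, 1)
  }
})

test_that("external engine requires a folding adapter", {
  expect_error(structure_features("GGGAAACCC", engine = "external"),
               "internal")
  ext <- structure_features("GGGAAACCC", engine = "external",
                            fold_fun = function(s) list(n_pairs = 3,
                                                        mfe = -2.1))
  expect_equal(ext[["nmfe"]], -2.1 / 9)
})

test_that("the feature vector is the documented 90-dim concatenation", {
  s <- toy_transcripts(2L)$seq[1L]
  v <- feature_vector(s)
  expect_length(v, 90L)
  expect_equal(v[1:84], kmer_freq(s))
  expect_equal(v[85:87], orf_features(s, find_orfs(s)))
  expect_equal(v[88:90], structure_features(s))
  expect_identical(v, feature_vector(s))
  expect_error(feature_vector("ATG"), "short")
  m <- feature_matrix(transcripts(c("a", "b"), c(strrep("ATGC", 60L),
                                                 strrep("GATTACA", 40L))))
  expect_equal(dim(m), c(2L, 90L))
})
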