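#' Clustering features: 1-mer and 2-mer frequencies
#'
#' The 20-dimensional vector (4 mononucleotide + 16 dinucleotide weighted
#' frequencies) used to cluster negative samples before undersampling;
#' computed by the same rule as the classical k-mer features restricted to
#' k in {1, 2} (weights `a_1 = 1/16`, `a_2 = 1/4`).
#'
#' @param seq Nucleotide string over A/C/G/T, length >= 2.
#' @return Named numeric vector of length 20.
#' @export
cluster_features <- function(seq) {
  if (nchar(seq) < 2L) stop("sequence too short for 2-mer features")
  kmer_freq(seq, ks = 1:2, k_max = 3L)
}

# round() as the conventional half-away-from-zero rounded function (R's
# round() is banker's rounding, which differs at exact .5 remainders).
round_half_up <- function(x) floor(x + 0.5)

#' Cluster negative samples on k-mer composition
#'
#' Runs k-means (k-means++-style seeding, then Lloyd iterations via
#' [stats::kmeans()]) on the 20-dim 1-mer/2-mer frequency vectors of the
#' negative samples. The number of centers defaults to 200 and is capped
#' at the number of distinct samples for small runs.
#'
#' @param neg Transcript `data.frame` of negative samples.
#' @param n_clusters Requested number of cluster centers (default 200).
#' @param seed Integer seed making seeding and assignment deterministic.
#' @return A list of class `cluster_plan`: `assignments` (cluster id per
#'   sample), `sizes` (x_i), `total`, `n_clusters`.
#' @export
cluster_negatives <- function(neg, n_clusters = 200L, seed = 1L) {
  feats <- t(vapply(neg$seq, cluster_features, numeric(20L)))
  n_clusters <- min(as.integer(n_clusters), nrow(unique(feats)))
  assignments <- with_seed(seed, {
    centers <- kmeanspp_centers(feats, n_clusters)
    km <- suppressWarnings(
      stats::kmeans(feats, centers = centers, iter.max = 50L))
    km$cluster
  })
  sizes <- tabulate(assignments, nbins = n_clusters)
  structure(list(assignments = assignments, sizes = sizes,
                 total = nrow(feats), n_clusters = n_clusters),
            class = "cluster_plan")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
    for (j in 2:k) {
      d2[d2 < 0] <- 0
      probs <- if (sum(d2) > 0) d2 else rep(1, n)
      idx[j] <- sample.int(n, 1L, prob = probs)
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Per-cluster undersampling counts
#'
#' From cluster i of size `x_i`, `O_i = round(x_i / total * target)`
#' samples are drawn, so the selection preserves the cluster composition
#' of the majority class. The raw rounded counts need not sum exactly to
#' `target`; with `exact_total = TRUE` a largest-remainder adjustment
#' (capped at cluster sizes) enforces the exact total.
#'
#' @param sizes Integer vector of cluster sizes x_i.
#' @param target Desired number of selected samples.
#' @param exact_total Apply the largest-remainder correction (default
#'   `FALSE`, keeping the raw rounded counts).
#' @return Integer vector O_i, same length as `sizes`.
#' @export
undersample_counts <- function(sizes, target, exact_total = FALSE) {
  total <- sum(sizes)
  if (target > total) stop("target exceeds the number of available samples")
  exact <- sizes / total * target
  o <- pmin(round_half_up(exact), sizes)
  if (exact_total) {
    delta <- target - sum(o)
    if (delta != 0L) {
      rem <- exact - o
      ord <- order(if (delta > 0L) -rem else rem)
      for (i in ord) {
        if (delta == 0L) break
        step <- sign(delta)
        if (o[i] + step >= 0L && o[i] + step <= sizes[i]) {
          o[i] <- o[i] + step
          delta <- delta - step
        }
      }
    }
  }
  as.integer(o)
}

#' Proportional undersampling of clustered negatives
#'
#' @param neg Transcript `data.frame` of negative samples.
#' @param plan `cluster_plan` from [cluster_negatives()] on the same
#'   samples.
#' @param target Desired number of negatives after undersampling.
#' @param seed Integer seed for the within-cluster draws.
#' @param exact_total Passed to [undersample_counts()].
#' @return Transcript `data.frame` of the selected negatives (a subset of
#'   `neg`, no duplicates).
#' @export
undersample <- function(neg, plan, target, seed = 1L, exact_total = FALSE) {
  stopifnot(inherits(plan, "cluster_plan"),
            length(plan$assignments) == nrow(neg))
  o <- undersample_counts(plan$sizes, target, exact_total = exact_total)
  keep <- with_seed(seed, {
    unlist(lapply(seq_len(plan$n_clusters), function(i) {
      members <- which(plan$assignments == i)
      if (o[i] == 0L) return(integer(0))
      members[sample.int(length(members), o[i])]
    }))
  })
  out <- neg[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a ratio-controlled labeled dataset
#'
#' Keeps all positives and undersamples the negatives (k-means clustering
#' plus proportional selection) down to `ratio` times the positive count,
#' producing the balanced (1:1) or imbalanced (1:2, 1:3) designs.
#'
#' @param pos Positive (lncRNA, label 1) transcript table.
#' @param neg Negative (mRNA, label 0) transcript table.
#' @param ratio Negatives per positive: 1, 2 or 3.
#' @param n_clusters Cluster count for the undersampling (default 200,
#'   capped at the number of negatives).
#' @param seed Integer seed.
#' @param exact_total Enforce the exact negative count (default `FALSE`;
#'   the raw per-cluster rounding may deviate by a few samples).
#' @return Labeled transcript `data.frame` (positives then selected
#'   negatives).
#' @export
make_ratio_dataset <- function(pos, neg, ratio = 1L, n_clusters = 200L,
                               seed = 1L, exact_total = FALSE) {
  stopifnot(ratio %in% 1:3)
  target <- ratio * nrow(pos)
  if (target > nrow(neg)) {
    stop("need ", target, " negatives for a 1:", ratio, " design but only ",
         nrow(neg), " are available")
  }
  plan <- cluster_negatives(neg, n_clusters = n_clusters, seed = seed)
  sel <- undersample(neg, plan, target, seed = seed,
                     exact_total = exact_total)
  pos$label <- 1L
  sel$label <- 0L
  out <- rbind(pos, sel)
  rownames(out) <- NULL
  out
}
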