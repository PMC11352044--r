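# All-combinations pairwise log-ratio aggregates.
#
# The pairwise estimators summarise log2(b_i / a_j) over the full Cartesian
# product of ordered (a_j, b_i) cross pairs.  Below `pair_cap` pairs the set
# is enumerated; above it both aggregates are still computed EXACTLY without
# materialising the n_a x n_b matrix:
#   * the mean over pairs of (log2 b_i - log2 a_j) collapses algebraically to
#     mean(log2 b) - mean(log2 a);
#   * the median is found by order-statistic selection on the implicit
#     pairwise-difference set (bisection on the value axis with rank counting,
#     then enumeration of the narrow band that contains the middle ranks) --
#     the same idea used for large-sample Hodges-Lehmann estimators.

pairs_lr_mean <- function(la, lb, pair_cap = 1e7) {
  # identical to enumerate-then-mean, at any size
  mean(lb) - mean(la)
}

pairs_lr_median <- function(la, lb, pair_cap = 1e7, band_cap = 2e4) {
  na <- length(la)
  nb <- length(lb)
  if (as.double(na) * nb <= pair_cap) {
    return(stats::median(rep(lb, times = na) - rep(la, each = nb)))
  }
  pairs_median_select(la, lb, band_cap = band_cap)
}

# Exact median of {lb_i - la_j} without enumeration: the two middle order
# statistics are located by rank-counting bisection on the value axis.
pairs_median_select <- function(la, lb, band_cap = 2e4) {
  la <- sort(la)
  lb <- sort(lb)
  n_pairs <- as.double(length(la)) * length(lb)
  k1 <- floor((n_pairs + 1) / 2)
  k2 <- ceiling((n_pairs + 1) / 2)
  v1 <- pairs_kth_select(la, lb, k1, band_cap)
  if (k2 == k1) v1 else (v1 + pairs_kth_select(la, lb, k2, band_cap)) / 2
}

# k-th smallest of the implicit pairwise-difference set {lb_i - la_j}.
# Invariant: cnt(<= lo) < k <= cnt(<= hi); bisect until the (lo, hi] band
# holds at most band_cap values, then enumerate the band.
pairs_kth_select <- function(la, lb, k, band_cap = 2e4) {
  na <- length(la)
  # number of pairs with lb_i - la_j <= t  (la_j >= lb_i - t)
  cnt_le <- function(t) sum(na - findInterval(lb - t, la, left.open = TRUE))
  lo <- min(lb) - max(la)
  lo <- lo - 1e-9 * (1 + abs(lo))   # strictly below the smallest pair value
  hi <- max(lb) - min(la)
  c_lo <- 0
  c_hi <- as.double(na) * length(lb)
  repeat {
    if (c_hi - c_lo <= band_cap) break
    mid <- (lo + hi) / 2
    # massive ties can pin the k-th value to a band narrower than one ulp;
    # every remaining candidate then equals hi to machine precision
    if (!(mid > lo && mid < hi)) return(hi)
    c_mid <- cnt_le(mid)
    if (c_mid >= k) {
      hi <- mid
      c_hi <- c_mid
    } else {
      lo <- mid
      c_lo <- c_mid
    }
  }
  # enumerate pair values in (lo, hi]: la_j in [lb_i - hi, lb_i - lo)
  j1 <- findInterval(lb - hi, la, left.open = TRUE) + 1L
  j2 <- findInterval(lb - lo, la, left.open = TRUE)
  keep <- which(j2 >= j1)
  lens <- j2[keep] - j1[keep] + 1L
  vals <- rep(lb[keep], lens) - la[sequence(lens, from = j1[keep])]
  sort(vals, partial = k - c_lo)[k - c_lo]
}

# One bootstrap pass shared by the *_bootstrap methods: resample a and b
# independently with replacement to their original sizes, recompute the pairs
# aggregate, average over `reps` replicates.  Caller seeds the RNG.
pairs_lr_bootstrap <- function(la, lb, agg = c("mean", "median"),
                               reps = 100L, pair_cap = 1e7) {
  agg <- match.arg(agg)
  na <- length(la)
  nb <- length(lb)
  vals <- vapply(seq_len(reps), function(r) {
    la_star <- la[sample.int(na, na, replace = TRUE)]
    lb_star <- lb[sample.int(nb, nb, replace = TRUE)]
    if (agg == "mean") {
      pairs_lr_mean(la_star, lb_star, pair_cap)
    } else {
      pairs_lr_median(la_star, lb_star, pair_cap)
    }
  }, numeric(1))
  mean(vals)
}
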