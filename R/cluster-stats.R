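#' Build a null distribution for a time-resolved statistic
#'
#' Three null constructions:
#' \describe{
#'   \item{label_shuffle}{Condition labels are permuted independently
#'     within each unit before recomputing the statistic (tests each time
#'     point against chance).  `x` is `list(tensor, labels)` and `stat_fn`
#'     maps `(tensor, labels)` to a numeric series.}
#'   \item{celltype_shuffle}{Units are reassigned at random to two
#'     pseudo-populations of the original sizes (tests a population
#'     difference).  `x` is `list(a, b)`, two units x bins matrices of a
#'     per-unit statistic; the statistic is the difference of population
#'     means.}
#'   \item{mixed_populations}{Units are pooled and split `k_mixes` times
#'     into two size-matched pseudo-populations; `index_fn` computes a
#'     per-population index series, and all `k(k-1)/2` pairwise
#'     differences per time point form the null (used for stability-index
#'     comparisons where each index requires a full decode).}
#' }
#'
#' @param x Mode-dependent input (see above).
#' @param mode Null construction.
#' @param iterations Iterations for modes 1-2 (>= 100 enforced).
#' @param stat_fn For `label_shuffle`: function(tensor, labels) -> series.
#' @param index_fn For `mixed_populations`: function(counts, labels) ->
#'   index series (one pseudo-population's stability index).
#' @param k_mixes Number of random mixes for mode 3 (46 in the full
#'   analysis).
#' @param seed RNG seed.
#' @return Iterations x bins matrix (modes 1-2) or pair-differences x bins
#'   matrix (mode 3).
#' @export
build_null <- function(x, mode = c("label_shuffle", "celltype_shuffle",
                                   "mixed_populations"),
                       iterations = 1000, stat_fn = NULL, index_fn = NULL,
                       k_mixes = 46, seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "mixed_populations" && iterations < 100) {
    stop("need at least 100 iterations for a stable percentile")
  }
  if (mode == "label_shuffle") {
    stopifnot(is.function(stat_fn))
    tensor <- x[[1]]
    labels <- x[[2]]
    counts <- tensor$counts
    nt <- dim(counts)[2]
    out <- with_seed(seed, {
      t(vapply(seq_len(iterations), function(it) {
        shuf <- tensor
        for (u in seq_len(dim(counts)[1])) {
          shuf$counts[u, , ] <- counts[u, sample(nt), ]
        }
        as.numeric(stat_fn(shuf, labels))
      }, numeric(length(stat_fn(tensor, labels)))))
    })
    return(out)
  }
  if (mode == "celltype_shuffle") {
    a <- x[[1]]
    b <- x[[2]]
    stopifnot(ncol(a) == ncol(b))
    pool <- rbind(a, b)
    na <- nrow(a)
    out <- with_seed(seed, {
      t(vapply(seq_len(iterations), function(it) {
        take <- sample(nrow(pool), na)
        colMeans(pool[take, , drop = FALSE]) -
          colMeans(pool[-take, , drop = FALSE])
      }, numeric(ncol(a))))
    })
    return(out)
  }
  # mixed_populations: each mix samples one size-matched pseudo-population
  # from the pooled units and computes its index series; the null is the
  # k(k-1)/2 pairwise differences between mix indices per time point
  stopifnot(is.function(index_fn))
  counts <- x$counts
  labels <- x$labels
  n_match <- x$n_match
  nu <- dim(counts)[1]
  stopifnot(n_match <= nu)
  mix_index <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(k_mixes), function(m) {
      pick <- sample(nu, n_match)
      as.numeric(index_fn(counts[pick, , , drop = FALSE], labels))
    }))
  })
  pairs <- utils::combn(k_mixes, 2)
  diffs <- matrix(NA_real_, ncol(pairs), ncol(mix_index))
  for (p in seq_len(ncol(pairs))) {
    diffs[p, ] <- mix_index[pairs[1, p], ] - mix_index[pairs[2, p], ]
  }
  attr(diffs, "mix_index") <- mix_index
  diffs
}

#' Maximum-sum cluster-based permutation test
#'
#' Candidate clusters are maximal runs of contiguous bins where the
#' observed series exceeds the per-bin `cluster_percentile` of the null;
#' each cluster's mass is the sum of the observed statistic over the run.
#' The null max-mass distribution is built by clustering every null
#' iteration against the same per-bin thresholds; a cluster's p-value is
#' the fraction of null max masses at or above its mass.
#'
#' @param observed Numeric series (bins).
#' @param null Iterations x bins null matrix.
#' @param cluster_percentile Per-bin threshold percentile (99.9).
#' @param alpha Cluster significance level (0.001).
#' @return List of class `cluster_result`: `clusters` data frame (start,
#'   end, mass, p, significant), `thresholds`, `null_max_mass`.
#' @export
cluster_permutation_test <- function(observed, null,
                                     cluster_percentile = 99.9,
                                     alpha = 0.001) {
  stopifnot(length(observed) == ncol(null))
  thr <- apply(null, 2, quantile, probs = cluster_percentile / 100,
               names = FALSE)
  runs_of <- function(series) {
    above <- series > thr & !is.na(series)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
  }
  obs_runs <- runs_of(observed)
  iters <- nrow(null)
  null_max <- vapply(seq_len(iters), function(it) {
    rr <- runs_of(null[it, ])
    if (!nrow(rr)) return(0)
    max(vapply(seq_len(nrow(rr)), function(i) {
      sum(null[it, rr[i, 1]:rr[i, 2]])
    }, numeric(1)))
  }, numeric(1))
  if (!is.matrix(obs_runs) || !nrow(obs_runs)) {
    return(structure(list(clusters = data.frame(start = integer(),
                                                end = integer(),
                                                mass = numeric(),
                                                p = numeric(),
                                                significant = logical()),
                          thresholds = thr, null_max_mass = null_max),
                     class = "cluster_result"))
  }
  clusters <- do.call(rbind, lapply(seq_len(nrow(obs_runs)), function(i) {
    mass <- sum(observed[obs_runs[i, 1]:obs_runs[i, 2]])
    p <- (sum(null_max >= mass) + 1) / (iters + 1)
    data.frame(start = as.integer(obs_runs[i, 1]),
               end = as.integer(obs_runs[i, 2]),
               mass = mass, p = p, significant = p < alpha)
  }))
  structure(list(clusters = clusters, thresholds = thr,
                 null_max_mass = null_max),
            class = "cluster_result")
}

#' Chi-square comparison of two proportions
#'
#' Standard 2x2 chi-square test of equal proportions, without continuity
#' correction.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return List with `statistic`, `p`, `prop1`, `prop2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  expect <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expect == 0)) {
    stop("expected cell count of zero; use an exact test")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       prop1 = k1 / n1, prop2 = k2 / n2)
}
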