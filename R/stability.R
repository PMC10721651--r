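#' Classify off-diagonal decoding bins as static
#'
#' An off-diagonal bin pair (tp1, tp2) is static when (i) the accuracy
#' drops from both corresponding on-diagonal bins,
#' `CTD(tp1,tp1) - CTD(tp1,tp2)` and `CTD(tp2,tp2) - CTD(tp1,tp2)`, are
#' each below the `diff_percentile` of the same differences in the null
#' stack, (ii) the off-diagonal accuracy itself exceeds the
#' `diff_percentile` of its null accuracies, and (iii) both on-diagonal
#' bins exceed their null at the Bonferroni-corrected level
#' `diag_alpha / n_bins` (0.0025 for 20 bins).  On-diagonal entries are 0
#' by convention.
#'
#' @param ctd A [cross_temporal_decode()] result (or list with `ctd` and
#'   `null`).
#' @param diff_percentile Percentile of the null accuracy-drop
#'   distributions below which a drop counts as absent (99.9).
#' @param chance_percentile Percentile of the null accuracies the
#'   off-diagonal accuracy must exceed (99.9).
#' @param diag_alpha Uncorrected alpha for the on-diagonal gate (0.05).
#' @return List of class `static_matrix`: `static` (0/1 matrix),
#'   `diag_sig` (logical), `diag_alpha_per_bin`.
#' @export
classify_static_bins <- function(ctd, diff_percentile = 99.9,
                                 chance_percentile = 99.9,
                                 diag_alpha = 0.05) {
  A <- ctd$ctd
  null <- ctd$null
  stopifnot(nrow(A) == ncol(A), all(dim(null)[1:2] == dim(A)))
  iters <- dim(null)[3]
  if (iters < 100) stop("need at least 100 null iterations")
  nb <- nrow(A)
  q <- diff_percentile / 100
  qa <- chance_percentile / 100

  # on-diagonal significance, Bonferroni over the diagonal bins
  alpha_bin <- diag_alpha / nb
  diag_sig <- vapply(seq_len(nb), function(k) {
    p <- (sum(null[k, k, ] >= A[k, k]) + 1) / (iters + 1)
    p < alpha_bin
  }, logical(1))

  static <- matrix(0L, nb, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (i == j) next
      if (!(diag_sig[i] && diag_sig[j])) next
      d1 <- A[i, i] - A[i, j]
      d2 <- A[j, j] - A[i, j]
      nd1 <- null[i, i, ] - null[i, j, ]
      nd2 <- null[j, j, ] - null[i, j, ]
      thr1 <- quantile(nd1, q, names = FALSE)
      thr2 <- quantile(nd2, q, names = FALSE)
      above <- A[i, j] > quantile(null[i, j, ], qa, names = FALSE)
      if (d1 < thr1 && d2 < thr2 && above) static[i, j] <- 1L
    }
  }
  structure(list(static = static, diag_sig = diag_sig,
                 diag_alpha_per_bin = alpha_bin,
                 diff_percentile = diff_percentile),
            class = "static_matrix")
}

#' Stability index per on-diagonal time bin
#'
#' For each on-diagonal bin k the raw index is the proportion of static
#' flags over row k and column k (diagonal excluded).  The smoothed index
#' is a moving average including the previous and next bin's rows/columns
#' (truncated at the edges).  Bins whose on-diagonal accuracy is not
#' significant are masked (smoothing first, masking second).
#'
#' @param static_matrix A [classify_static_bins()] result.
#' @param joint_sig Optional additional significance mask (e.g. the
#'   intersection with another population for a two-population
#'   comparison).
#' @return Data frame with bin, raw, smoothed, masked.
#' @export
stability_index <- function(static_matrix, joint_sig = NULL) {
  S <- static_matrix$static
  nb <- nrow(S)
  sig <- static_matrix$diag_sig
  if (!is.null(joint_sig)) sig <- sig & joint_sig
  raw <- vapply(seq_len(nb), function(k) {
    (sum(S[k, -k]) + sum(S[-k, k])) / (2 * (nb - 1))
  }, numeric(1))
  smoothed <- vapply(seq_len(nb), function(k) {
    mean(raw[max(1, k - 1):min(nb, k + 1)])
  }, numeric(1))
  if (!any(sig)) warning("no significant on-diagonal bins; all masked")
  data.frame(bin = seq_len(nb), raw = raw, smoothed = smoothed,
             masked = !sig)
}

#' Bootstrap SD of the stability index
#'
#' Repeats the full decode (observed + null), static classification and
#' stability index `n_boot` times, resampling units with replacement, and
#' reports the per-bin standard deviation of the smoothed index.
#'
#' @param tensor,labels As for [cross_temporal_decode()].
#' @param n_boot Bootstrap resamples (50 in the full analysis).
#' @param runs,folds,shuffles Decode parameters per resample.
#' @param diff_percentile,diag_alpha Static-classification parameters.
#' @param seed RNG seed.
#' @return List with `sd` (per-bin SD of the smoothed index), `indices`
#'   (n_boot x bins matrix, masked bins NA).
#' @export
bootstrap_stability_sd <- function(tensor, labels, n_boot = 50,
                                   runs = 5, folds = 10, shuffles = 200,
                                   diff_percentile = 99.9,
                                   diag_alpha = 0.05, seed = 1L) {
  nu <- dim(tensor$counts)[1]
  idx <- NULL
  res <- NULL
  for (b in seq_len(n_boot)) {
    dec <- cross_temporal_decode(tensor, labels, n_units_match = nu,
                                 folds = folds, runs = runs,
                                 shuffles = shuffles,
                                 replace_units = TRUE,
                                 seed = stream_seed(seed,
                                                    paste0("boot", b)))
    st <- classify_static_bins(dec, diff_percentile, diag_alpha)
    si <- stability_index(st)
    v <- si$smoothed
    v[si$masked] <- NA_real_
    res <- rbind(res, v)
  }
  list(sd = apply(res, 2, sd, na.rm = TRUE), indices = res)
}
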