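#' Maximum-correlation-coefficient classifier
#'
#' Units are z-scored with the training mean and SD (computed over all
#' training pseudotrials, all conditions, and applied to both training and
#' test data); each condition's template is the mean training vector; the
#' prediction is the condition whose template has the highest Pearson
#' correlation with the test vector.  Exact ties are broken uniformly at
#' random (session RNG); units with zero training SD are dropped.
#'
#' @param train_x Training matrix, pseudotrials x units.
#' @param train_labels Condition per training pseudotrial.
#' @param test_x Test vector (one pseudotrial, length = units).
#' @return The predicted condition label.
#' @export
max_corr_classifier <- function(train_x, train_labels, test_x) {
  train_labels <- as.factor(train_labels)
  stopifnot(ncol(train_x) == length(test_x))
  mu <- colMeans(train_x)
  sdev <- apply(train_x, 2, sd)
  keep <- sdev > 0
  if (!any(keep)) return(sample(levels(train_labels), 1))
  z_train <- sweep(sweep(train_x[, keep, drop = FALSE], 2, mu[keep]),
                   2, sdev[keep], "/")
  z_test <- (test_x[keep] - mu[keep]) / sdev[keep]
  templ <- apply(z_train, 2, function(col) tapply(col, train_labels, mean))
  r <- suppressWarnings(stats::cor(z_test, t(templ)))
  r[is.na(r)] <- -Inf
  if (all(!is.finite(r))) return(sample(levels(train_labels), 1))
  best <- which(r == max(r))
  levels(train_labels)[if (length(best) > 1) sample(best, 1) else best]
}

# build the pseudotrial array for one resampling run:
# units x conditions x n_pseudo x bins, sampling trial indices
# independently per unit within condition (pseudo-population)
sample_pseudotrials <- function(counts, idx_by_cond, n_pseudo) {
  nu <- dim(counts)[1]
  nb <- dim(counts)[3]
  nc <- length(idx_by_cond)
  out <- array(NA_real_, c(nu, nc, n_pseudo, nb))
  for (u in seq_len(nu)) {
    for (ci in seq_len(nc)) {
      take <- sample(idx_by_cond[[ci]], n_pseudo)
      out[u, ci, , ] <- counts[u, take, ]
    }
  }
  out
}

# accuracy matrix (bins x bins) for one pseudotrial array via
# leave-one-pseudotrial-out over the n_pseudo slots
decode_pseudo_array <- function(ps) {
  decode_accuracy_cpp(as.numeric(ps), as.integer(dim(ps)))
}

#' Cross-temporal population decoding
#'
#' Trains and tests the maximum-correlation classifier on every pair of
#' time bins.  Per run, `n_units_match` units are sampled (without
#' replacement unless `replace_units`) and `folds` trials per condition
#' per unit are drawn independently (pseudo-population); decoding uses
#' leave-one-pseudotrial-out cross-validation and accuracies are averaged
#' over folds, then runs.  The null stack repeats the procedure with
#' condition labels permuted independently within each unit (one
#' permutation per iteration, reused across all bin pairs).
#'
#' @param tensor A [bin_spikes()] tensor over the IS period (50 ms bins).
#' @param labels Condition per trial.
#' @param n_units_match Units per run (default all units).
#' @param folds Pseudotrials per condition (10, split 9 train / 1 test).
#' @param runs Resampling runs for the observed matrix (50 in the full
#'   analysis).
#' @param shuffles Null iterations (1000 in the full analysis).
#' @param replace_units Sample units with replacement (used by the
#'   stability bootstrap).
#' @param seed RNG seed.
#' @return List of class `ctd`: `ctd` (bins x bins accuracy), `null`
#'   (bins x bins x shuffles), `centers_s`, `chance`, `n_units`, `runs`.
#' @export
cross_temporal_decode <- function(tensor, labels, n_units_match = NULL,
                                  folds = 10, runs = 50, shuffles = 1000,
                                  replace_units = FALSE, seed = 1L) {
  counts <- tensor$counts
  if (anyNA(counts)) {
    ok_bins <- apply(!is.na(counts), 3, all)
    counts <- counts[, , ok_bins, drop = FALSE]
    centers <- tensor$centers_s[ok_bins]
  } else {
    centers <- tensor$centers_s
  }
  labels <- as.factor(labels)
  stopifnot(length(labels) == dim(counts)[2])
  idx_by_cond <- split(seq_along(labels), labels)
  if (min(lengths(idx_by_cond)) < folds) {
    stop("fewer trials than folds in some condition")
  }
  nu_all <- dim(counts)[1]
  nu <- if (is.null(n_units_match)) nu_all else n_units_match
  if (!replace_units && nu > nu_all) stop("not enough units to match")
  nb <- dim(counts)[3]
  nc <- nlevels(labels)

  acc <- matrix(0, nb, nb)
  null <- array(NA_real_, c(nb, nb, shuffles))
  with_seed(seed, {
    for (r in seq_len(runs)) {
      us <- if (nu == nu_all && !replace_units) seq_len(nu_all) else
        sample(nu_all, nu, replace = replace_units)
      ps <- sample_pseudotrials(counts[us, , , drop = FALSE],
                                idx_by_cond, folds)
      acc <- acc + decode_pseudo_array(ps) / runs
    }
    for (it in seq_len(shuffles)) {
      us <- if (nu == nu_all && !replace_units) seq_len(nu_all) else
        sample(nu_all, nu, replace = replace_units)
      sub <- counts[us, , , drop = FALSE]
      # permute condition labels independently within each unit by
      # permuting that unit's trial axis
      for (u in seq_len(nu)) {
        sub[u, , ] <- sub[u, sample(dim(sub)[2]), ]
      }
      ps <- sample_pseudotrials(sub, idx_by_cond, folds)
      null[, , it] <- decode_pseudo_array(ps)
    }
  })
  structure(list(ctd = acc, null = null, centers_s = centers,
                 chance = 1 / nc, n_units = nu, runs = runs,
                 folds = folds),
            class = "ctd")
}

#' Rescale a cross-temporal matrix to [0, 1] for display
#'
#' Affine rescaling of the accuracy matrix so its minimum maps to 0 and
#' its maximum to 1.  Display only: all statistics operate on raw
#' accuracies.
#'
#' @param ctd A `ctd` object or a numeric matrix.
#' @return The rescaled matrix.
#' @export
normalize_ctm <- function(ctd) {
  A <- if (inherits(ctd, "ctd")) ctd$ctd else ctd
  rng <- range(A)
  if (rng[1] == rng[2]) {
    warning("constant accuracy matrix; returning 0.5 everywhere")
    return(matrix(0.5, nrow(A), ncol(A)))
  }
  (A - rng[1]) / (rng[2] - rng[1])
}
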