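# Independent oracles used across tests; deliberately coded by different
# routes than the package implementations they check.

# Brute-force per-mask mean: loop over every pixel of the image.
brute_force_mask_mean <- function(img_mat, label_mat, label) {
  tot <- 0
  n <- 0
  for (i in seq_len(nrow(img_mat))) {
    for (j in seq_len(ncol(img_mat))) {
      if (label_mat[i, j] == label) {
        tot <- tot + img_mat[i, j]
        n <- n + 1
      }
    }
  }
  tot / n
}

# Brute-force dip-type statistic, O(n^3), for small samples. Uses the chord
# characterisation of convex hulls: the greatest convex minorant of points
# (x, F) evaluated at x_j is the minimum over all chords (i, k) with
# i <= j <= k of the chord's value at x_j; the least concave majorant is the
# corresponding maximum. For each candidate mode the statistic takes the
# worst deviation on either side, and halves the best achievable maximum.
brute_force_dip <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (length(unique(x)) < 3) {
    return(0)
  }
  f <- (seq_len(n) - 0.5) / n
  if (any(duplicated(x))) {
    f <- as.numeric(tapply(f, match(x, unique(x)), mean))
    x <- unique(x)
    n <- length(x)
  }
  chord <- function(i, k, xq) {
    if (i == k) {
      return(f[i])
    }
    f[i] + (f[k] - f[i]) * (xq - x[i]) / (x[k] - x[i])
  }
  # deviation of F above the lower convex hull of points idx
  conv_dev <- function(idx) {
    dev <- 0
    for (j in idx) {
      lo <- Inf
      for (i in idx[idx <= j]) {
        for (k in idx[idx >= j]) {
          lo <- min(lo, chord(i, k, x[j]))
        }
      }
      dev <- max(dev, f[j] - lo)
    }
    dev
  }
  conc_dev <- function(idx) {
    dev <- 0
    for (j in idx) {
      hi <- -Inf
      for (i in idx[idx <= j]) {
        for (k in idx[idx >= j]) {
          hi <- max(hi, chord(i, k, x[j]))
        }
      }
      dev <- max(dev, hi - f[j])
    }
    dev
  }
  best <- Inf
  for (m in seq_len(n)) {
    d <- max(conv_dev(seq_len(m)), conc_dev(m:n))
    best <- min(best, d)
  }
  best / 2
}

# match detected soma ROIs to ground-truth labels; best IoU per truth soma
match_rois_iou <- function(det_labels, truth_labels) {
  n_truth <- max(truth_labels)
  out <- data.frame(truth = seq_len(n_truth), best_iou = 0)
  if (max(det_labels) == 0) {
    return(out)
  }
  truth_sizes <- tabulate(truth_labels[truth_labels > 0], nbins = n_truth)
  det_sizes <- tabulate(det_labels[det_labels > 0], nbins = max(det_labels))
  sel <- truth_labels > 0 & det_labels > 0
  if (!any(sel)) {
    return(out)
  }
  pairs <- table(truth = truth_labels[sel], det = det_labels[sel])
  for (ti in rownames(pairs)) {
    t_id <- as.integer(ti)
    for (di in colnames(pairs)) {
      inter <- pairs[ti, di]
      if (inter == 0) next
      d_id <- as.integer(di)
      iou <- inter / (truth_sizes[t_id] + det_sizes[d_id] - inter)
      if (iou > out$best_iou[t_id]) out$best_iou[t_id] <- iou
    }
  }
  out
}
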