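# Independent brute-force oracles for the information-theoretic and
# ranking machinery.  These work directly on joint count tables / all pairs
# and never call the package's own estimators.

# Entropy in bits from a vector of category counts.
entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Mutual information in bits from a joint count table, by the exhaustive
# double sum over the joint distribution.
mi_oracle <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

su_oracle <- function(joint) {
  hx <- entropy_oracle(rowSums(joint))
  hy <- entropy_oracle(colSums(joint))
  if (hx + hy == 0) return(0)
  2 * mi_oracle(joint) / (hx + hy)
}

# Expand a joint count table into the two aligned categorical columns.
joint_to_columns <- function(joint) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      x <- c(x, rep(i, joint[i, j]))
      y <- c(y, rep(j, joint[i, j]))
    }
  }
  list(x = x, y = y)
}

# All 2 x 2 joint count tables summing to exactly n.
all_2x2_tables <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (d in 0:(n - a - b)) {
    out[[length(out) + 1L]] <- matrix(c(a, b, d, n - a - b - d), 2, 2)
  }
  out
}

# AUC by exhaustive pair counting: P(score+ > score-) + 0.5 P(tie).
auc_pairs_oracle <- function(truth, scores) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Independent greedy mRMR (MID) evaluation on discretized columns, scoring
# every candidate at every step from first principles via mi_oracle.
mrmr_oracle <- function(d, y, k) {
  mi_cols <- function(u, v) mi_oracle(table(u, v))
  p <- ncol(d)
  rel <- vapply(seq_len(p), function(j) mi_cols(d[, j], y), numeric(1))
  picked <- integer(0)
  for (t in seq_len(min(k, p))) {
    remaining <- setdiff(seq_len(p), picked)
    crit <- vapply(remaining, function(j) {
      if (!length(picked)) rel[j]
      else rel[j] - mean(vapply(picked, function(s) mi_cols(d[, j], d[, s]),
                                numeric(1)))
    }, numeric(1))
    # same tie rule as the package documents: equal criteria (to numerical
    # tolerance) resolve to the lower column index
    picked <- c(picked, remaining[which(crit >= max(crit) - 1e-12)[1]])
  }
  picked
}

# Direct evaluation of the confusion-matrix formulas, written independently
# of compute_metrics().
metrics_oracle <- function(tp, tn, fp, fn) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- sqrt((tp + fn)) * sqrt((tp + fp)) * sqrt((tn + fn)) * sqrt((tn + fp))
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sn = div0(tp, tp + fn),
       sp = div0(tn, tn + fp),
       pre = div0(tp, tp + fp),
       f = div0(2 * tp, 2 * tp + fp + fn),
       mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}
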