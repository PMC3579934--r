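# Independent oracles kept deliberately naive: full enumeration for exact
# Wilcoxon p-values, O(n_pos * n_neg) pair counting and trapezoidal
# integration for AUC, and a loop-based altered-probe caller. They share no
# code with the package implementations they check.

# two-sided exact rank-sum p by enumeration of all C(n+m, n) group labelings
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(r), nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# two-sided exact signed-rank p by enumeration of all 2^n sign assignments
oracle_signedrank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# tie-aware AUC by brute force over all positive/negative pairs
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# trapezoidal area of a stored ROC curve
oracle_auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# loop-based altered-probe caller (strict threshold)
oracle_altered_probes <- function(bm, donor, recipient, threshold) {
  hits <- character(0)
  for (i in seq_along(bm$probe_ids)) {
    bd <- bm$beta[i, donor]; br <- bm$beta[i, recipient]
    if (!is.na(bd) && !is.na(br) && abs(br - bd) > threshold) {
      hits <- c(hits, bm$probe_ids[i])
    }
  }
  sort(hits)
}

random_profile <- function(amplicon = "NBL2", n = 6) {
  methylation_profile(amplicon, stats::runif(n, 0, 100))
}
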