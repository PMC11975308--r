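# shared fixtures, all generated in code

small_cohort <- function(n = 120, seed = 11, ...) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# a directly constructed pair_set with separable features: positives sit at
# higher feature values, pairs progress between scans
toy_pair_set <- function(n = 80, seed = 3, noise = 0.2, horizon = 2) {
  set.seed(seed)
  half <- n %/% 2
  y2 <- c(rep(1L, half), rep(0L, n - half))
  y1 <- rep(0L, n)
  sev1 <- stats::runif(n, 0, 1.5)
  sev2 <- sev1 + ifelse(y2 == 1, stats::runif(n, 1.5, 2.5),
                        stats::runif(n, 0, 0.5))
  d <- 4
  w <- rep(1, d) / sqrt(d)
  X1 <- outer(sev1, w) + matrix(stats::rnorm(n * d, 0, noise), n, d)
  X2 <- outer(sev2, w) + matrix(stats::rnorm(n * d, 0, noise), n, d)
  structure(list(X1 = X1, X2 = X2, y1 = y1, y2 = y2,
                 has2 = rep(TRUE, n),
                 subject_id = sprintf("T%03d", seq_len(n)),
                 grade1 = pmin(4L, floor(sev1)), grade2 = pmin(4L, floor(sev2)),
                 set_id = ifelse(y2 == 1, "set1", "set2"),
                 horizon = horizon), class = "pair_set")
}

# exhaustive pairwise AUROC oracle (ties counted one half)
brute_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# step-wise average precision by direct counting at each distinct threshold
brute_auprc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# brute-force maximum-cardinality one-to-one matching by recursive enumeration
brute_max_matching <- function(adj) {
  # adj: logical matrix cases x controls
  best <- 0L
  recurse <- function(ci, used) {
    if (ci > nrow(adj)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(ci + 1L, used)  # leave this case unmatched
    for (cj in which(adj[ci, ] & !used)) {
      used[cj] <- TRUE
      recurse(ci + 1L, used)
      used[cj] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ncol(adj)))
  best
}

# risk1/risk2 pairs from a scan-level prediction frame
paired_risks <- function(pred) {
  p1 <- pred[pred$scan_index == 1, ]
  p2 <- pred[pred$scan_index == 2, ]
  i <- match(p2$subject_id, p1$subject_id)
  data.frame(risk1 = p1$risk[i], risk2 = p2$risk)
}
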