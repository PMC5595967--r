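# Independent oracles, deliberately naive, used to cross-check the package's
# implementations.

# Exhaustive agglomerative complete-linkage clustering: keeps explicit member
# lists and rescans all pairs at every step. Returns the merge heights in
# merge order.
bf_complete_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Brute-force cytotoxicity call: explicit loop over compounds.
bf_cytotoxic <- function(compound_viability, dmso, k) {
  thr <- mean(dmso) - k * sd(dmso)
  hits <- character(0)
  for (i in seq_len(nrow(compound_viability))) {
    if (compound_viability$viability_pct[i] < thr) {
      hits <- c(hits, compound_viability$compound[i])
    }
  }
  hits
}

# Second-path Z': mean and sd recomputed from sums rather than mean()/sd().
bf_zprime <- function(pos, neg) {
  m <- function(x) sum(x) / length(x)
  sdev <- function(x) sqrt(sum((x - m(x))^2) / (length(x) - 1))
  1 - 3 * (sdev(pos) + sdev(neg)) / abs(m(pos) - m(neg))
}

# Two-value sample with an exact mean and exact sample SD.
pair_with <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)

# Random valid fingerprint (percent scale, sums to 100).
random_fingerprint <- function() {
  x <- runif(4)
  100 * x / sum(x)
}
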