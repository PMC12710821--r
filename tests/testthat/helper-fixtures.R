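# fixtures and independent oracles used across test files

# small cohort wrapper: desk-scale defaults for fast unit tests
tinyCohort <- function(n = 20, P = 20, T = 100, seed = 1, ...) {
  generateCohort(cohortSpec(nSubjects = n, parcelsPerHemi = P,
                            timepoints = T, seed = seed, ...))
}

nullAsymmetry <- function() {
  data.frame(netA = character(), netB = character(), offset = numeric())
}

# brute-force elementwise Pearson correlation (independent of stats::cor)
oraclePearson <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- X[i, ] - mean(X[i, ]); b <- X[j, ] - mean(X[j, ])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  out
}

# binary MCC as the Pearson correlation of the label indicator vectors
# reconstructed from a 2x2 confusion matrix (independent computational route)
oracleMccBinary <- function(cm) {
  truth <- c(rep(0, cm[1, 1] + cm[1, 2]), rep(1, cm[2, 1] + cm[2, 2]))
  pred <- c(rep(0, cm[1, 1]), rep(1, cm[1, 2]), rep(0, cm[2, 1]), rep(1, cm[2, 2]))
  r <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(r)) 0 else r
}

# Benjamini-Hochberg by explicit step-up enumeration
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  for (k in (m - 1L):1L) ranked[k] <- min(ranked[k], ranked[k + 1L])
  out <- numeric(m)
  out[o] <- pmin(ranked, 1)
  out
}

# two Gaussian clouds that are linearly separable
separableClouds <- function(n = 30, p = 5, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = gap), n, p))
  list(x = X, y = rep(c("A", "B"), each = n))
}
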