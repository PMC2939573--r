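# Independent oracles used to validate the package's exact tests and the
# birth-death richness law. These deliberately use different mechanisms
# than the implementation (literal enumeration matrices; event-level
# Gillespie simulation).

# All 2^m signed sums of a contrast vector (literal enumeration).
bruteSignedSums <- function(v) {
  m <- length(v)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  as.vector(signs %*% v)
}

# Two-tailed sign-permutation p by literal enumeration.
bruteSignPermP <- function(x) {
  x <- x[x != 0]
  s <- abs(bruteSignedSums(x))
  obs <- abs(sum(x))
  mean(s >= obs - 1e-9)
}

# Exact signed-rank p by literal enumeration of all 2^m sign patterns on
# the realized tie-averaged ranks.
bruteWilcoxP <- function(x, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  ranks <- rank(abs(x))
  m <- length(x)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W <- as.vector(grid %*% ranks)
  Wobs <- sum(ranks[x > 0])
  if (alternative == "greater") {
    return(mean(W >= Wobs - 1e-9))
  }
  Wneg <- sum(ranks) - Wobs
  hi <- max(Wobs, Wneg)
  lo <- min(Wobs, Wneg)
  min(1, mean(W >= hi - 1e-9) + mean(W <= lo + 1e-9))
}

# Event-level (Gillespie) linear birth-death population simulator from one
# stem lineage over time t; returns the extant count (0 = extinct). This is
# the mechanistic counterpart of the closed-form geometric richness law.
gillespieCladeSize <- function(reps, t, lambda, mu) {
  vapply(seq_len(reps), function(i) {
    n <- 1L
    tm <- 0
    while (n > 0L) {
      tot <- n * (lambda + mu)
      w <- stats::rexp(1L, tot)
      if (tm + w >= t) break
      tm <- tm + w
      n <- n + if (stats::runif(1L) < lambda / (lambda + mu)) 1L else -1L
    }
    n
  }, integer(1))
}

# Chi-square goodness of fit of observed clade sizes against the
# survival-conditioned geometric law with parameter beta, pooling the tail
# so all expected counts are >= 5.
geometricGofP <- function(sizes, beta) {
  stopifnot(all(sizes >= 1))
  N <- length(sizes)
  k <- 1L
  probs <- numeric(0)
  while (TRUE) {
    p <- (1 - beta) * beta^(k - 1)
    if (N * p < 5 || k > 10000L) break
    probs <- c(probs, p)
    k <- k + 1L
  }
  tailP <- 1 - sum(probs)
  obs <- c(tabulate(pmin(sizes, k), nbins = k - 1L)[seq_len(k - 1L)],
           sum(sizes >= k))
  suppressWarnings(stats::chisq.test(obs, p = c(probs, tailP))$p.value)
}

# A small fixed richness tree used across rate-shift tests.
toyRichnessTree <- function() {
  readRichnessTree("((A:10,B:10):10,C:20);", c(A = 5, B = 3, C = 10))
}
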