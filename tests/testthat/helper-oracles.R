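# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths.

# Levenshtein distance by dynamic programming (oracle for the fuzzy matcher,
# which uses utils::adist internally)
lev_oracle <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  d[n + 1, m + 1]
}

# Fisher exact p by full enumeration of all tables with the observed
# margins, probabilities from lchoose (no dhyper)
fisher_enum_oracle <- function(a, b, c, d, sided = "two") {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  pobs <- p[xs == a]
  if (sided == "one") min(1, sum(p[xs >= a]))
  else min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# BH q-values straight from the min-over-tail definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# brute-force 2x2 from a corpus: entity exposure vector vs rolled-up event
contingency_oracle <- function(exposed, has_event) {
  c(a = sum(exposed & has_event), b = sum(exposed & !has_event),
    c = sum(!exposed & has_event), d = sum(!exposed & !has_event))
}

random_table <- function(nmax = 40) {
  repeat {
    cells <- as.integer(rmultinom(1, sample(4:nmax, 1), runif(4, 0.05, 1)))
    return(cells)
  }
}
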