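# Brute-force verification oracles: everything is computed by expanding the
# contingency table into individual (forecast, observed) events and looping,
# with no marginal/matrix shortcuts shared with the implementation.

expand_events <- function(counts) {
  f <- integer(0); o <- integer(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      n <- counts[i, j]
      if (n > 0) { f <- c(f, rep(i, n)); o <- c(o, rep(j, n)) }
    }
  }
  list(f = f, o = o)
}

oracle_hit_rate <- function(counts, i) {
  ev <- expand_events(counts)
  hits <- 0; obs <- 0
  for (e in seq_along(ev$f)) {
    if (ev$o[e] == i) {
      obs <- obs + 1
      if (ev$f[e] == i) hits <- hits + 1
    }
  }
  if (obs == 0) NA_real_ else hits / obs
}

oracle_far <- function(counts, i) {
  ev <- expand_events(counts)
  fc <- 0; fa <- 0
  for (e in seq_along(ev$f)) {
    if (ev$f[e] == i) {
      fc <- fc + 1
      if (ev$o[e] != i) fa <- fa + 1
    }
  }
  if (fc == 0) NA_real_ else fa / fc
}

oracle_marginals <- function(counts) {
  ev <- expand_events(counts)
  k <- nrow(counts)
  nf <- no <- numeric(k); hits <- 0
  for (e in seq_along(ev$f)) {
    nf[ev$f[e]] <- nf[ev$f[e]] + 1
    no[ev$o[e]] <- no[ev$o[e]] + 1
    if (ev$f[e] == ev$o[e]) hits <- hits + 1
  }
  list(nf = nf, no = no, hits = hits, N = length(ev$f), k = k)
}

oracle_heidke <- function(counts) {
  m <- oracle_marginals(counts)
  num <- m$hits / m$N - sum(m$nf * m$no) / m$N^2
  den <- 1 - sum(m$nf * m$no) / m$N^2
  if (den == 0) NA_real_ else num / den
}

oracle_peirce <- function(counts) {
  m <- oracle_marginals(counts)
  num <- m$hits / m$N - sum(m$nf * m$no) / m$N^2
  den <- 1 - sum(m$no^2) / m$N^2
  if (den == 0) NA_real_ else num / den
}

# direct transcription of the equitable-score construction, then a per-event
# average of the scoring-matrix entries
oracle_gerrity <- function(counts) {
  m <- oracle_marginals(counts)
  k <- m$k
  p <- m$no / m$N
  a <- numeric(k - 1)
  for (i in seq_len(k - 1)) {
    cum <- sum(p[1:i])
    a[i] <- (1 - cum) / cum
  }
  s <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      lo <- min(i, j); hi <- max(i, j)
      term1 <- 0
      if (lo > 1) for (r in 1:(lo - 1)) term1 <- term1 + 1 / a[r]
      term2 <- -(hi - lo)
      term3 <- 0
      if (hi <= k - 1) for (r in hi:(k - 1)) term3 <- term3 + a[r]
      s[i, j] <- (term1 + term2 + term3) / (k - 1)
    }
  }
  ev <- expand_events(counts)
  total <- 0
  for (e in seq_along(ev$f)) total <- total + s[ev$f[e], ev$o[e]]
  total / m$N
}

# random k x k table with non-empty first and last observed columns, so that
# all cumulative observed frequencies are strictly inside (0, 1) and the
# Gerrity matrix is defined
random_table <- function(k = sample(2:7, 1), max_count = 3) {
  counts <- matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
  counts[sample(k, 1), 1] <- counts[sample(k, 1), 1] + 1L
  counts[sample(k, 1), k] <- counts[sample(k, 1), k] + 1L
  counts
}
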