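# Independent brute-force oracles for the automatic thresholds. These
# re-derive each criterion from its published definition, scanning every
# candidate gray level, and stay independent of the package's code paths.

# Huang & Wang minimum fuzziness, evaluated per pixel
huang_bruteforce <- function(values) {
  v <- as.numeric(values)
  lev <- sort(unique(v))
  C <- max(lev) - min(lev)
  best <- Inf
  bt <- NA
  for (t in lev[-length(lev)]) {
    mu0 <- mean(v[v <= t])
    mu1 <- mean(v[v > t])
    mu <- ifelse(v <= t, 1 / (1 + abs(v - mu0) / C),
                 1 / (1 + abs(v - mu1) / C))
    s <- ifelse(mu >= 1 - 1e-12, 0, -mu * log(mu) - (1 - mu) * log(1 - mu))
    e <- sum(s)
    if (e < best - 1e-9) {
      best <- e
      bt <- t
    }
  }
  bt
}

# Tsai moment preservation: scan every candidate threshold, solve the
# two-level image that preserves the first two moments at that split, and
# keep the split whose third moment is closest to the input's
moments_bruteforce <- function(values) {
  v <- as.numeric(values)
  lev <- sort(unique(v))
  m1 <- mean(v); m2 <- mean(v^2); m3 <- mean(v^3)
  s2 <- m2 - m1^2
  best <- Inf
  bt <- NA
  for (t in lev[-length(lev)]) {
    p <- mean(v <= t)
    if (p <= 0 || p >= 1) next
    za <- m1 - sqrt((1 - p) / p * s2)
    zb <- m1 + sqrt(p / (1 - p) * s2)
    d <- abs(p * za^3 + (1 - p) * zb^3 - m3)
    if (d < best - 1e-12) {
      best <- d
      bt <- t
    }
  }
  bt
}

# independent 8-connected component count by queue-based flood fill
count_components_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!m[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            m[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}
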