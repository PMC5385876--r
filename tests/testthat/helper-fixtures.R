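# Small deterministic fixtures built in code.

synthetic_index_ids <- paste0("I", 1:10)
synthetic_orientation <- spectreff::default_orientation(synthetic_index_ids)

recovery_actives <- c("P2", "P5", "P9", "P12")

# independent loop-based implementation of the grey relational equations,
# kept deliberately naive (scalar loops) as the oracle
grey_oracle <- function(reference, comparatives, rho = 0.5) {
  m <- ncol(comparatives)
  n <- length(reference)
  dev <- matrix(0, n, m)
  for (i in seq_len(m)) for (k in seq_len(n)) {
    dev[k, i] <- abs(reference[k] - comparatives[k, i])
  }
  d_min <- Inf; d_max <- -Inf
  for (i in seq_len(m)) for (k in seq_len(n)) {
    if (dev[k, i] < d_min) d_min <- dev[k, i]
    if (dev[k, i] > d_max) d_max <- dev[k, i]
  }
  xi <- matrix(1, n, m)
  if (d_max > 0) {
    for (i in seq_len(m)) for (k in seq_len(n)) {
      xi[k, i] <- (d_min + rho * d_max) / (dev[k, i] + rho * d_max)
    }
  }
  grd <- numeric(m)
  for (i in seq_len(m)) grd[i] <- sum(xi[, i]) / n
  list(coefficients = xi, grd = grd, d_min = d_min, d_max = d_max)
}

# direct triple-loop centered L2 discrepancy oracle
cd2_oracle <- function(levels) {
  n <- nrow(levels); s <- ncol(levels)
  u <- (levels - 0.5) / n
  t1 <- 0
  for (i in seq_len(n)) {
    p <- 1
    for (j in seq_len(s)) {
      a <- abs(u[i, j] - 0.5)
      p <- p * (1 + 0.5 * a - 0.5 * a^2)
    }
    t1 <- t1 + p
  }
  t2 <- 0
  for (i in seq_len(n)) for (k in seq_len(n)) {
    p <- 1
    for (j in seq_len(s)) {
      ai <- abs(u[i, j] - 0.5); ak <- abs(u[k, j] - 0.5)
      p <- p * (1 + 0.5 * ai + 0.5 * ak - 0.5 * abs(u[i, j] - u[k, j]))
    }
    t2 <- t2 + p
  }
  unname(sqrt((13 / 12)^s - 2 * t1 / n + t2 / n^2))
}
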