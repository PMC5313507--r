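# Independent oracles used by the test suite. These deliberately avoid the
# package's own algorithms: the DTW oracle enumerates monotone alignment
# paths recursively, the regression oracle solves the normal equations
# directly, the FDR oracle spells out the step-up rule.

# Brute-force DTW: minimum over all monotone alignment paths from (1, 1)
# to (l1, l2) of the summed squared differences (square root taken at the
# end). Exponential-time path recursion with cost pruning; exact for the
# short series used in tests.
dtw_bruteforce <- function(x1, x2) {
  l1 <- length(x1)
  l2 <- length(x2)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (x1[i] - x2[j])^2
    if (acc >= best) return(invisible())
    if (i == l1 && j == l2) {
      best <<- acc
      return(invisible())
    }
    if (i < l1 && j < l2) rec(i + 1L, j + 1L, acc)
    if (i < l1) rec(i + 1L, j, acc)
    if (j < l2) rec(i, j + 1L, acc)
  }
  rec(1L, 1L, 0)
  sqrt(best)
}

# Least-squares residual through the normal equations.
residual_oracle <- function(x, C) {
  X <- cbind(1, as.matrix(C))
  beta <- solve(t(X) %*% X, t(X) %*% x)
  as.numeric(x - X %*% beta)
}

# Benjamini-Hochberg step-up, spelled out.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= q * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(below) > 0L) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Shared small fixture: deterministic band-limited pair.
surrogate_pair <- function(seed, n = 150L, tr = 2) {
  list(x1 = gen_surrogate(n, tr, seed = seed),
       x2 = gen_surrogate(n, tr, seed = seed + 50000L))
}
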