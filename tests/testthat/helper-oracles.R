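# Independent oracles, deliberately naive: plain loops and generic linear
# algebra, sharing no code path with the package internals they check.

# Marginal penetrance by explicit summation over the joint n-locus
# genotype distribution.
oracle_marginal <- function(mafs, values, locus, genotype) {
  n <- length(mafs)
  freqs <- lapply(mafs, function(q) {
    p <- 1 - q
    c(p^2, 2 * p * q, q^2)
  })
  num <- 0
  den <- 0
  for (idx in 0:(3^n - 1)) {
    g <- integer(n)
    rem <- idx
    for (i in n:1) {
      g[i] <- rem %% 3
      rem <- rem %/% 3
    }
    if (g[locus] != genotype) next
    w <- 1
    for (i in seq_len(n)) if (i != locus) w <- w * freqs[[i]][g[i] + 1]
    num <- num + w * values[idx + 1]
    den <- den + w
  }
  num / den
}

# Heritability by brute-force arithmetic over every cell.
oracle_heritability <- function(mafs, values) {
  n <- length(mafs)
  freqs <- lapply(mafs, function(q) {
    p <- 1 - q
    c(p^2, 2 * p * q, q^2)
  })
  K <- 0
  for (idx in 0:(3^n - 1)) {
    g <- integer(n)
    rem <- idx
    for (i in n:1) {
      g[i] <- rem %% 3
      rem <- rem %/% 3
    }
    w <- 1
    for (i in seq_len(n)) w <- w * freqs[[i]][g[i] + 1]
    K <- K + w * values[idx + 1]
  }
  V <- 0
  for (idx in 0:(3^n - 1)) {
    g <- integer(n)
    rem <- idx
    for (i in n:1) {
      g[i] <- rem %% 3
      rem <- rem %/% 3
    }
    w <- 1
    for (i in seq_len(n)) w <- w * freqs[[i]][g[i] + 1]
    V <- V + w * (values[idx + 1] - K)^2
  }
  V / (K * (1 - K))
}

# Completion of seeded cells to a line-feasible table by generic row
# reduction: stack the homogeneous line system with pinning equations for
# the seeded cells and solve the (overdetermined, consistent) system by
# least squares.
oracle_complete <- function(cells, seed_values, n, mafs) {
  A <- epistasim::constraint_matrix(epistasim::enumerate_lines(n, mafs))
  E <- matrix(0, length(cells), 3^n)
  E[cbind(seq_along(cells), cells)] <- 1
  M <- rbind(A, E)
  rhs <- c(rep(0, nrow(A)), seed_values)
  qr.solve(M, rhs)
}

# 3-binomial-standard-error band around a reported proportion.
within_3se <- function(p_hat, p_ref, n_trials) {
  abs(p_hat - p_ref) <= 3 * sqrt(p_ref * (1 - p_ref) / n_trials)
}
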