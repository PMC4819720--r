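# fixtures built in code: small stacks, matrices and signals

random_cm <- function(P, seed, sd = 0.2, labels = paste0("R", seq_len(P))) {
  taylorconn:::with_seed(seed, {
    connectivity_matrix(
      sym_from_upper(stats::rnorm(P * (P - 1) / 2, 0, sd), P, labels))
  })
}

small_stack <- function(P = 10, D = 3, seed = 42) {
  gen_stack(synthetic_spec(P, D, seed = seed))
}

# pure tone helper: A * sin(2 pi f t + phase)
tone <- function(f, fs, dur, A = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  A * sin(2 * pi * f * t + phase)
}

# brute-force triple-loop matrix product (independent oracle)
triple_loop_product <- function(A, B) {
  P <- nrow(A)
  out <- matrix(0, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      acc <- 0
      for (k in seq_len(P)) acc <- acc + A[i, k] * B[k, j]
      out[i, j] <- acc
    }
  }
  out
}

# exact Mann-Whitney by bitmask enumeration with pairwise counting
# (independent of the rank-based implementation)
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  u_null <- c()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != na) next
    u_null <- c(u_null, u_of(pooled[idx], pooled[-idx]))
  }
  mu <- na * (n - na) / 2
  list(U = u_obs, p = mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12))
}
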