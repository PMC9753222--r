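# independent combinatorial oracles used by the acceptance checks

# exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N
# with the first K elements marked
enum_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# exact two-tailed Mann-Whitney p by full enumeration of group assignments
enum_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  vals <- c(x, y)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  Us <- apply(combn(n, n1), 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu))
}
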