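# Independent brute-force oracle for small HMM chains: enumerate every state
# path, accumulate joint log-probabilities directly, and derive the best path
# and the per-site marginals. Deliberately shares no code with the package's
# dynamic-programming implementation.

enum_decode <- function(E, log_trans_array) {
  n <- nrow(E)
  S <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  logp <- apply(paths, 1, function(pth) {
    s <- -log(S) + E[1, pth[1]]
    if (n > 1) {
      for (i in 2:n) s <- s + log_trans_array[i - 1, pth[i - 1], pth[i]] + E[i, pth[i]]
    }
    s
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  post <- matrix(0, n, S)
  for (i in seq_len(n)) {
    for (s in seq_len(S)) {
      sel <- paths[, i] == s
      if (any(sel)) {
        ms <- max(logp[sel])
        post[i, s] <- exp(ms + log(sum(exp(logp[sel] - ms))) - loglik)
      }
    }
  }
  list(best_loglik = m, best_path = paths[which.max(logp), ],
       posterior = post, loglik = loglik)
}

# random valid emission/transition instances for property tests
random_hmm_instance <- function(n, S) {
  E <- matrix(rnorm(n * S, sd = 2), n, S)
  arr <- array(0, c(max(n - 1, 1), S, S))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      M <- matrix(rexp(S * S), S, S)
      M <- M / rowSums(M)
      arr[i, , ] <- log(M)
    }
  }
  list(E = E, arr = arr)
}
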