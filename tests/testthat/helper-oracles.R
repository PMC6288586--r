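# Independent oracles, written from the defining formulas rather than the
# package's implementation path.

# naive O(N^2) direct-DFT version of the smoothing chain:
# Hamming multiply -> forward DFT -> low-pass mask -> inverse DFT ->
# real part -> Hamming divide
naive_smooth <- function(x, alpha) {
  N <- length(x)
  k <- 0:(N - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (N - 1))
  a <- w * x
  s <- vapply(k, function(kk) {
    sum(a * exp(-2i * pi * (0:(N - 1)) * kk / N))
  }, complex(1))
  s[abs(k - N / 2) < N / 2 - alpha] <- 0
  u <- vapply(k, function(kk) {
    sum(s * exp(2i * pi * (0:(N - 1)) * kk / N)) / N
  }, complex(1))
  Re(u) / w
}

# exhaustive nearest-neighbour search: the largest index p whose history
# satisfies d(x, h_p) <= d(x, h_i) for all i
brute_nn <- function(ls, test_history) {
  K <- nrow(ls$histories)
  d <- vapply(seq_len(K), function(i) {
    sqrt(sum((ls$histories[i, ] - test_history)^2))
  }, numeric(1))
  p <- NA_integer_
  for (i in seq_len(K)) {
    if (all(d[i] <= d)) p <- i # keeps the largest satisfying index
  }
  ls$futures[p, ]
}

rms <- function(a, b) sqrt(mean((a - b)^2))
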