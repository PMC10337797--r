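# Independent oracles, deliberately naive: plain nested loops over the
# definition, no shared code with the package internals.

# I(X;Y) = sum_x sum_y p(x,y) log2( p(x,y) / (p(x) p(y)) )
mi_brute_force <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      pxy <- counts[i, j] / n
      if (pxy > 0) {
        px <- sum(counts[i, ]) / n
        py <- sum(counts[, j]) / n
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

entropy_brute_force <- function(probs) {
  total <- 0
  for (p in probs) if (p > 0) total <- total - p * log2(p)
  total
}

binary_entropy <- function(p) {
  entropy_brute_force(c(p, 1 - p))
}

# random sparse-ish count table up to max_dim x max_dim
random_count_table <- function(max_dim = 10, max_count = 20) {
  nr <- sample(2:max_dim, 1)
  nc <- sample(2:max_dim, 1)
  m <- matrix(rpois(nr * nc, lambda = runif(1, 0.3, 3)), nr, nc)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}
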