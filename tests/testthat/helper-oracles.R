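# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, closed forms, and
# combinatorial enumeration only.

# Adjusted Rand index between two label vectors (Hubert & Arabie form).
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(length(x))
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Elementwise topological overlap by explicit loops.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# One-tailed hypergeometric tail P(overlap >= k) by direct enumeration over
# binomial coefficients (no phyper).
hyper_tail_oracle <- function(k, set_size, universe_size, draw_size) {
  js <- k:min(set_size, draw_size)
  sum(choose(set_size, js) * choose(universe_size - set_size, draw_size - js)) /
    choose(universe_size, draw_size)
}

# EASE score oracle: hypergeometric tail after removing one list hit from
# both the hit count and the list size.
ease_oracle <- function(lh, lt, ph, pt) {
  if (lh <= 1) return(1)
  hyper_tail_oracle(lh - 1, ph, pt, lt - 1)
}

# Small standard designs reused across tests.
three_module_design <- function(seed, n_background = 0, samples = 40,
                                loading = 0.9, noise = 0.5) {
  per_group <- c(A = ceiling(samples / 4), B = floor(samples / 4),
                 C = ceiling(samples / 4) , D = samples -
                   2 * ceiling(samples / 4) - floor(samples / 4))
  synthetic_design(
    modules = list(module_spec("M1", 100, loading, trait_effect = 0.6),
                   module_spec("M2", 80, loading),
                   module_spec("M3", 60, loading, trait_effect = -0.4)),
    n_background_genes = n_background,
    samples_per_group = per_group,
    noise_sd = noise, seed = seed)
}
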