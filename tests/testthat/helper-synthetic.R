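# Small, fast generator configurations reused across tests.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_compounds = 200L, n_models = 3L,
                   n_submodels_per_model = 5L, n_substructure_bits = 20L,
                   fingerprint_bits = 32L, seed = 42L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# brute-force Tanimoto double loop, kept independent of the package path
brute_similarity <- function(query, train) {
  t(sapply(seq_len(nrow(query)), function(i) {
    sims <- sapply(seq_len(nrow(train)), function(j) {
      a <- query[i, ] != 0
      b <- train[j, ] != 0
      un <- sum(a | b)
      if (un == 0) 0 else sum(a & b) / un
    })
    c(max = max(sims), mean = mean(sims))
  }))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1)))[ro]
}

# brute-force hypergeometric upper tail by choose() summation
brute_hyper_tail <- function(aw, at, iw, it) {
  n_with <- aw + iw
  n_total <- at + it
  ks <- seq(aw, min(n_with, at))
  sum(choose(n_with, ks) * choose(n_total - n_with, at - ks)) /
    choose(n_total, at)
}
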