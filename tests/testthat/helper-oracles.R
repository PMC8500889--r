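# Independent oracles used across the test files.

# brute-force per-cue product form of the context-model similarity
similarity_product_oracle <- function(probe, exemplar, s) {
  prod(ifelse(probe == exemplar, 1, s))
}

# exact posterior median of s under the original exemplar model, with the
# precision integrated out analytically:
#   p(s | y) propto (b + SSE(s)/2)^-(a + n/2) on [0, 1]
# evaluated by dense 1-D quadrature; independent of the MCMC code path.
exact_original_median <- function(dat, a = 0.001, b = 0.001, ngrid = 4001) {
  mem <- memory_from_data(dat)
  probes <- as.matrix(dat[grep("^cue_", names(dat))])
  n <- nrow(dat)
  sg <- seq(1e-6, 1 - 1e-6, length.out = ngrid)
  lp <- vapply(sg, function(s) {
    pred <- predict_batch(probes, mem, s)
    -(a + n / 2) * log(b + sum((dat$response - pred)^2) / 2)
  }, numeric(1))
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  sg[which.min(abs(cdf - 0.5))]
}

random_binary_matrix <- function(n, d) {
  matrix(sample(0:1, n * d, replace = TRUE), n, d)
}

# small dataset generated at the main study conditions
make_dataset <- function(s_true, recall_prob, seed, noise_sd = 0) {
  set.seed(seed)
  design <- simulate_design()
  generate_judgments(design, generation_regime(s_true, recall_prob, noise_sd))
}
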