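# shared fixtures built in code

# the bundled progressively censored ball-bearing data, inline for tests
# that exercise the file reader against a known-good object
bb_times <- c(0.1788, 0.3300, 0.4152, 0.4560, 0.4848, 0.5186, 0.5196,
              0.5412, 0.5556, 0.6780, 0.6864, 0.8412, 0.9312, 0.9864,
              1.0584, 1.2792, 1.2804, 1.7340)
bb_removals <- c(rep(0L, 11), 1L, 0L, 1L, 0L, 1L, 0L, 2L)
bb_scheme <- censoring_scheme(23, 18, bb_removals)
bb_sample <- prog_cens_sample(bb_scheme, bb_times)
bb_beta <- 0.332

toy_sample <- function() {
  prog_cens_sample(censoring_scheme(8, 5, c(1L, 0L, 1L, 0L, 1L)),
                   c(0.3, 0.5, 0.9, 1.4, 2.2))
}

# random valid parameter sets for property-style loops
random_phfd <- function(k, seed = 101) {
  set.seed(seed)
  lapply(seq_len(k), function(i)
    phfd(alpha = runif(1, 0.2, 5), beta = runif(1, -0.8, 3)))
}
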