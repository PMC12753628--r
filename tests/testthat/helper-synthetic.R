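# Small cohort specifications used across tests.

small_spec <- function(n_features = 40L, n_human = 120L, n_monkey = 60L,
                       n_pos_human = 30L, n_pos_monkey = 18L,
                       divergent_idx = 1:8, informative_idx = 9:12,
                       low_icc_idx = 31:34, ...) {
  synthetic_spec(n_human = n_human, n_monkey = n_monkey,
                 n_pos_human = n_pos_human, n_pos_monkey = n_pos_monkey,
                 n_features = n_features, divergent_idx = divergent_idx,
                 informative_idx = informative_idx,
                 low_icc_idx = low_icc_idx, ...)
}

# Tiny deterministic image/mask pair for extraction tests.
toy_image <- function(seed = 7L, size = 24L) {
  img <- simulate_disc_image("human", grade = 2, seed = seed, size = size)
  list(image = img$image, mask = img$mask)
}
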