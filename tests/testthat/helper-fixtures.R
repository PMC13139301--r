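# Shared fixtures: everything is generated in code at test time.

# a small architecture (nonstandard widths) for fast training/forward tests
tiny_model_config <- function(compound_vocab_size = 12L,
                              compound_global_in = 20L,
                              protein_global_in = 15L,
                              seed = 5L) {
  model_config(compound_vocab_size = compound_vocab_size,
               protein_vocab_size = 21L,
               compound_global_in = compound_global_in,
               protein_global_in = protein_global_in,
               embedding_dim = 8L, conv_filters = c(6L, 8L, 10L),
               compound_kernels = c(2L, 3L, 3L),
               protein_kernels = c(2L, 3L, 4L),
               compound_local_out = 10L, protein_local_out = 10L,
               compound_global_out = 16L, protein_global_out = 16L,
               fusion_hidden = c(24L, 12L), dropout = 0.1,
               random_seed = seed, nonstandard = TRUE)
}

# a random feature batch matching tiny_model_config, with prefix-contiguous
# token rows (tokens pad only at the tail, like real encodings)
tiny_feature_batch <- function(n, cfg, seed = 1L, y = NULL) {
  withr::with_seed(seed, {
    comp_tokens <- matrix(0L, n, 100L)
    prot_tokens <- matrix(0L, n, 1000L)
    for (i in seq_len(n)) {
      lc <- sample(5:60, 1)
      comp_tokens[i, seq_len(lc)] <- sample.int(cfg$compound_vocab_size, lc,
                                                replace = TRUE)
      lp <- sample(20:150, 1)
      prot_tokens[i, seq_len(lp)] <- sample.int(21L, lp, replace = TRUE)
    }
    list(comp_tokens = comp_tokens,
         comp_global = matrix(rnorm(n * cfg$compound_global_in), n),
         prot_tokens = prot_tokens,
         prot_global = matrix(rnorm(n * cfg$protein_global_in), n),
         y = y %||% rnorm(n))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small learnable dataset + prepared features, built once per test file
small_training_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- generate_cpi_dataset(40, 6, 0.7, signal_spec(noise_sd = 0),
                               seed = 404)
    fz <- fit_featurizer(ds)
    feats <- prepare_features(fz, ds)
    w <- cpifuse:::featurizer_widths(fz)
    cfg <- model_config(compound_vocab_size = w$compound_vocab_size,
                        protein_vocab_size = w$protein_vocab_size,
                        compound_global_in = w$compound_global_in,
                        protein_global_in = w$protein_global_in,
                        random_seed = 7L)
    cache <<- list(ds = ds, fz = fz, feats = feats, cfg = cfg,
                   n = n_interactions(ds))
    cache
  }
})

write_cpi_fixture_csv <- function(path, rows) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
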