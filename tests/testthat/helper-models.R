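# Shared tiny configurations and cached fixtures for the test suite.
# Widths are deliberately small so every test runs in seconds; the
# architecture (5 GIN layers, 11 heads) is unchanged.

tiny_config <- function(seed = 1L, dropout = 0.1) {
  encoder_config(d = 16L, emb_hidden = 8L, dropout = dropout, seed = seed)
}

tiny_model <- function(seed = 1L) init_model(tiny_config(seed, dropout = 0))

# A 50-molecule structural sample drawn once from the curated pool.
toy_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixtures("aromatic-label", 50, seed = 1234)$smiles
    }
    cache
  }
})
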