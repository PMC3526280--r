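# Session-level cache so the expensive seeded fixture analyses are computed
# once and shared across test files.

.mm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .mm_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .mm_cache)
  }
  get(key, envir = .mm_cache, inherits = FALSE)
}

# a complete analysis of one fixture under the default seed: simulation,
# context model, detection, discovery, assignment, threshold
fixture_run <- function(name, seed = 1234L) {
  cached(paste0("run_", name, "_", seed), {
    fx <- make_fixture(name, seed = seed)
    model <- build_context_model(fx$genome, fx$ref_tracks)
    records <- detect_modifications(fx$tracks, fx$genome, model)
    hits <- top_hits(records, 1000L)
    windows <- extract_windows(hits, fx$genome)
    candidates <- discover_motifs(windows, fx$genome)
    records <- assign_hits(records, candidates, fx$genome)
    threshold <- select_threshold(
      records, if (name == "bce") 0.05 else 0.01)
    c(fx, list(model = model, records = records, hits = hits,
               windows = windows, candidates = candidates,
               threshold = threshold))
  })
}

planted_nonnuisance <- function(run) {
  dplyr::filter(run$motifs, !nuisance)
}

motif_key <- function(df) sort(paste(df$pattern, df$offset))
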