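# cached benchmark-community fits shared across the end-to-end checks
# (the same simulated community and fit serve the recovery and the
# reshuffling-null analyses, so each seed is fitted once)
.bench_cache <- new.env(parent = emptyenv())

bench_spec <- function(seed) {
  community_spec(n_taxa = 10, T = 350, L_true = 20,
                 self_coefficient = -0.4, n_inter_edges = 12,
                 inter_magnitude = c(0.3, 0.6), sequencing_depth = 1e5,
                 detection_floor = 0, seed = seed)
}

bench_fit <- function(seed) {
  key <- paste0("fit", seed)
  if (!exists(key, .bench_cache)) {
    gc <- suppressWarnings(generate_community(bench_spec(seed)))
    cfg <- run_config(seed = seed)
    ps <- preprocess(gc$table, cfg)
    tensor <- fit_all_responses(ps, cfg)
    edges <- extract_edges(tensor)
    strong <- mark_strong(edges, cfg$strong_percentile, site = "bench")
    assign(key, list(gc = gc, cfg = cfg, ps = ps, tensor = tensor,
                     edges = edges, strong = strong), .bench_cache)
  }
  get(key, .bench_cache)
}

bench_null <- function(seed) {
  key <- paste0("null", seed)
  if (!exists(key, .bench_cache)) {
    f <- bench_fit(seed)
    assign(key, null_run(f$ps, f$cfg, f$strong), .bench_cache)
  }
  get(key, .bench_cache)
}

n_strong_pairs <- function(edges) {
  s <- edges[edges$strong, , drop = FALSE]
  length(unique(paste(s$cause, s$effect)))
}
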