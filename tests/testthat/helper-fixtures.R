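# Shared fixtures: tiny deterministic datasets and cached simulation runs.

tiny_counts <- function() {
  m <- matrix(c(5, 0, 2,
                1, 1, 0,
                0, 4, 4,
                2, 2, 2,
                0, 0, 6,
                3, 1, 1), nrow = 6, byrow = TRUE,
              dimnames = list(paste0("c", 1:6), paste0("g", 1:3)))
  m
}

tiny_dataset <- function(labels = c("A", "A", "B", "B", "A", "B")) {
  labeled_dataset(tiny_counts(), labels = labels)
}

# Small two-reference collection used by several unit tests.
small_collection <- function(seed = 7, unseen = "type4") {
  cfg <- simulation_config(
    n_refs = 2, global_types = paste0("type", 1:4), cells_per_type = 50,
    query_cells_per_type = 40, n_genes = 800, n_markers_per_type = 20,
    unseen_type = unseen, seed = seed)
  simulate_collection(cfg)
}

# Scaled-down pipeline settings for the small collection.
small_run <- function(coll, seed = 11, ...) {
  annotate_query(coll$references, coll$query, n_top = 300, epochs = 40,
                 learning_rate = 3e-3, hidden = c(32, 16), seed = seed, ...)
}

# Cache shared across test files within one run (helpers are sourced once).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The three full-size leave-one-type-out study runs (one per seed, rotating
# the held-out type), reused by the end-to-end acceptance checks.
easy_runs <- function() {
  cached("easy_runs", {
    types <- paste0("type", 1:5)
    lapply(1:3, function(i) {
      cfg <- simulation_config(unseen_type = types[i], seed = 100 + i)
      coll <- simulate_collection(cfg)
      res <- annotate_query(coll$references, coll$query, n_top = 500,
                            epochs = 40, learning_rate = 3e-3,
                            hidden = c(64, 32), seed = 100 + i)
      list(coll = coll, res = res)
    })
  })
}

# A heterogeneous batch of small leave-one-type-out studies for the
# metric-complementarity property: regimes differ in sequencing depth,
# dropout, batch shift, marker strength and reference count, mirroring a
# benchmark collection spanning technologies. In a single homogeneous
# regime one metric can dominate every run, and an average cannot out-win
# its best component pairwise; the complementarity claim is about
# heterogeneous test collections.
het_runs <- function(n_runs = 24) {
  cached(paste0("het_runs_", n_runs), {
    grid <- expand.grid(
      depth = c(0.5, 1.5, 3), dropout = c(0, 0.2, 0.4),
      batch = c(0.15, 0.4), effect = c(1.2, 2))
    grid <- grid[rep(seq_len(nrow(grid)), length.out = n_runs), ]
    types <- paste0("type", 1:4)
    lapply(seq_len(n_runs), function(s) {
      g <- grid[s, ]
      held <- types[1 + (s %% 4)]
      cfg <- simulation_config(
        n_refs = 2 + (s %% 2), global_types = types, cells_per_type = 50,
        query_cells_per_type = 40, n_genes = 800, n_markers_per_type = 20,
        marker_effect = g$effect, baseline_log_mean = g$depth,
        batch_shift_sd = g$batch, dropout_rate = g$dropout,
        unseen_type = held, seed = 400 + s)
      coll <- simulate_collection(cfg)
      res <- small_run(coll, seed = 400 + s)
      list(coll = coll, res = res)
    })
  })
}
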