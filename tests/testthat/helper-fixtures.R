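# Shared fixtures, built lazily and cached for the whole test run.
# Heavy artifacts (full-scale lookup tables, the QUEST+ likelihood matrix)
# are built once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# reduced-grid preset: seconds-scale, for structural/logic tests
test_tab <- function(metric = "euclidean")
  fixture(paste0("test_tab_", metric),
          build_lookup_table(metric, preset = "test", seed = 42))

# full-scale tables: used wherever numerical accuracy matters
full_tab <- function(metric = "euclidean")
  fixture(paste0("full_tab_", metric),
          build_lookup_table(metric, preset = "full", seed = 42))

the_grid <- function() fixture("grid", quest_grid())

full_lik <- function()
  fixture("full_lik", quest_likelihood_matrix(the_grid(), full_tab()))

linear_observer <- function(w, slope = 1, metric = "euclidean")
  generating_observer(w, positional_mapping("linear", slope, slope), metric)

# n trials on pairs drawn uniformly (with replacement) from the full range
random_trials <- function(observer, n, seed) {
  pairs <- pair_table(3)
  idx <- withr::with_seed(seed, sample.int(nrow(pairs), n, replace = TRUE))
  simulate_fixed_pairs(observer, pairs[idx, ], 1, seed = seed)
}

# toy QUEST+ state with hand-filled likelihood columns (one row per combo)
toy_quest_state <- function(L, posterior = NULL) {
  Lf <- pmin(pmax(L, 1e-6), 1 - 1e-6)
  SL <- Lf * log(Lf) + (1 - Lf) * log1p(-Lf)
  pairs <- pair_table(1)[seq_len(ncol(L)), ]
  structure(list(posterior = posterior %||% rep(1 / nrow(L), nrow(L)),
                 candidates = seq_len(ncol(L)),
                 lik = structure(list(L = L, SL = SL, pairs = pairs),
                                 class = "cm_quest_lik"),
                 range = 1, n_trials = 0L),
            class = "cm_quest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
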