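# Shared fixtures: fast centroid-based models on small synthetic batches.

centroid_spec <- function() score_model_spec("centroid")

# small exchangeable batches (no drift) for conformal property tests
small_batches <- function(n = 400, d = 8, active_fraction = 0.3, seed = 1,
                          drift_delta = 0) {
  generate_batches(drift_scenario(
    n_train = n, n_test = n, n_score = n, d = d,
    active_fraction = active_fraction, drift_delta = drift_delta, seed = seed))
}

# a fitted centroid ICP on a 70/30 split of the train batch
small_icp <- function(b, seed = 1) {
  sp <- stratified_split(b$train$y, 0.3, seed = seed)
  fit_icp(b$train$x[sp$prop, ], b$train$y[sp$prop],
          b$train$x[sp$cal, ], b$train$y[sp$cal],
          spec = centroid_spec(), seed = seed)
}

# brute-force conformal p-value: literal recount, independent of the
# vectorised implementation
oracle_pvalue <- function(cal, t) {
  n_ge <- 0L
  for (c in cal) if (c >= t) n_ge <- n_ge + 1L
  (n_ge + 1) / (length(cal) + 1)
}

# parse a SMILES into a molecule graph (test-only shortcut)
smiles_graph <- function(smi) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))[[1]]
  molecule_graph(sdf)
}
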