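# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force average precision: walks every distinct threshold
# and accumulates recall-increment x precision directly from confusion
# counts. O(n^2); used only on tiny instances as the oracle for pr_auc().
ap_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0; P <- sum(labels)
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Gaussian-feature slice for fitting tests: k features, the first `n_signal`
# of which are shifted by `effect` in the positive class.
make_gaussian_slice <- function(n = 200, k = 3, n_signal = 1, effect = 2,
                                seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("f", seq_len(k))))
  if (n_signal > 0)
    X[, seq_len(n_signal)] <- X[, seq_len(n_signal), drop = FALSE] +
      effect * y
  list(X = X, labels = y)
}

# Minimal hand-built expression dataset: counts is cells x genes.
make_tiny_dataset <- function(id = "D1", counts, cell_type, sample_id,
                              disease_state, normalized = FALSE) {
  ds <- expression_dataset(
    dataset_id = id, counts = counts,
    gene_ids = paste0("g", seq_len(ncol(counts))),
    cell_ids = paste0(id, "_c", seq_len(nrow(counts))),
    cell_type = cell_type, sample_id = sample_id,
    disease_state = disease_state)
  if (normalized) ds <- normalize_log1p(ds)
  ds
}

# Two-dataset cohort config with a planted additive signature in the shared
# cell type; defaults match the recovery study conditions (log2 effect 2.0,
# batch sd 0.2, enough cells for >= 300 per class per dataset).
recovery_config <- function(seed, genes = c("g5", "g9"),
                            log2_effects = c(2, 2),
                            batch_log_sd = 0.2,
                            samples_per_dataset = 20,
                            cells_per_sample_per_type = 40,
                            n_genes = 100) {
  simulation_config(
    n_datasets = 2,
    samples_per_dataset = samples_per_dataset,
    disease_fraction = 0.5,
    cell_types_per_dataset = list("Goblet", "Goblet"),
    cells_per_sample_per_type = cells_per_sample_per_type,
    n_genes = n_genes,
    nb_dispersion = 10,
    batch_log_sd = batch_log_sd,
    signatures = list(signature_spec("Goblet", genes, log2_effects)),
    seed = seed)
}

# A fake ranked candidate list for selection tests: each entry mimics the
# model_candidate contract (model + train_metrics$pr_auc).
fake_candidate <- function(features, ops, train_auc) {
  list(model = formula_model(features, ops),
       train_metrics = list(pr_auc = train_auc))
}
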