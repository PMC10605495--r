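#' Planted gene-signature specification
#'
#' Describes the ground-truth disease signal for one cell type in a
#' simulated cohort: which genes shift, by how much (log2 fold change of
#' mean expression in disease vs healthy cells), and whether the per-gene
#' effects act independently (`additive`) or are coupled through a shared
#' per-cell activation (`multiplicative`). Emulates the 2-3-gene signatures
#' that small symbolic classifiers recover from real data.
#'
#' @param cell_type cell-type label the signature is planted in.
#' @param genes 1--3 distinct gene identifiers.
#' @param log2_effects per-gene signed log2 fold change (same length as
#'   `genes`).
#' @param interaction `"additive"` (default) or `"multiplicative"`.
#' @return a `signature_spec`.
#' @export
signature_spec <- function(cell_type, genes, log2_effects,
                           interaction = c("additive", "multiplicative")) {
  genes <- as.character(genes)
  if (!length(genes) %in% 1:3 || anyDuplicated(genes))
    stop_classed("sigtransfer_config",
                 "signature needs 1-3 distinct genes")
  if (length(log2_effects) != length(genes))
    stop_classed("sigtransfer_config",
                 "log2_effects must match genes in length")
  structure(list(cell_type = cell_type, genes = genes,
                 log2_effects = as.numeric(log2_effects),
                 interaction = match.arg(interaction)),
            class = "signature_spec")
}

#' Simulation recipe for a multi-dataset synthetic cohort
#'
#' Encodes the study conditions the simulator reproduces: several datasets
#' with distinct per-gene batch effects, patients (samples) labeled
#' healthy/disease, partially overlapping cell-type sets across datasets,
#' and a small planted signature per cell type driving the disease state.
#' Counts follow a negative binomial (gamma-Poisson) model, the standard
#' noise model for single-cell counts.
#'
#' @param n_datasets number of datasets (>= 2).
#' @param samples_per_dataset samples (patients) per dataset; scalar or
#'   per-dataset vector.
#' @param disease_fraction probability a sample is disease-labeled; scalar
#'   or per-dataset vector, in (0, 1).
#' @param cell_types_per_dataset list (length `n_datasets`) of cell-type
#'   label vectors; sets may overlap across datasets.
#' @param cells_per_sample_per_type mean cell count per (sample, type);
#'   realized counts are Poisson.
#' @param n_genes size of the shared gene panel (genes "g1".."gN").
#' @param baseline_log_mean_range interval for the per-gene baseline
#'   natural-log mean, drawn uniformly.
#' @param nb_dispersion negative-binomial size (shape) parameter; variance
#'   is `mu + mu^2 / nb_dispersion`.
#' @param batch_log_sd sd of the per-dataset, per-gene natural-log-scale
#'   batch shift (0 disables batch effects).
#' @param signatures list of [signature_spec()] objects, keyed internally
#'   by their cell types (at most one per type).
#' @param seed integer seed; equal configs generate bit-identical cohorts.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 2,
                              samples_per_dataset = 20,
                              disease_fraction = 0.4,
                              cell_types_per_dataset = NULL,
                              cells_per_sample_per_type = 30,
                              n_genes = 200,
                              baseline_log_mean_range = c(-1, 2),
                              nb_dispersion = 10,
                              batch_log_sd = 0.3,
                              signatures = list(),
                              seed = 1) {
  if (n_datasets < 2)
    stop_classed("sigtransfer_config", "need at least 2 datasets")
  if (is.null(cell_types_per_dataset))
    cell_types_per_dataset <- rep(list("TypeA"), n_datasets)
  if (length(cell_types_per_dataset) != n_datasets)
    stop_classed("sigtransfer_config",
                 "cell_types_per_dataset must have one set per dataset")
  samples_per_dataset <- rep_len(samples_per_dataset, n_datasets)
  disease_fraction <- rep_len(disease_fraction, n_datasets)
  if (any(disease_fraction <= 0 | disease_fraction >= 1))
    stop_classed("sigtransfer_config", "disease_fraction must be in (0,1)")
  if (nb_dispersion <= 0)
    stop_classed("sigtransfer_config", "nb_dispersion must be positive")
  panel <- paste0("g", seq_len(n_genes))
  if (length(signatures)) {
    if (!all(vapply(signatures, inherits, logical(1), "signature_spec")))
      stop_classed("sigtransfer_config",
                   "signatures must be signature_spec objects")
    names(signatures) <- vapply(signatures, `[[`, character(1), "cell_type")
    bad <- setdiff(unlist(lapply(signatures, `[[`, "genes")), panel)
    if (length(bad))
      stop_classed("sigtransfer_config",
                   "signature gene(s) outside the panel: %s",
                   paste(bad, collapse = ", "))
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 samples_per_dataset = as.integer(samples_per_dataset),
                 disease_fraction = disease_fraction,
                 cell_types_per_dataset = cell_types_per_dataset,
                 cells_per_sample_per_type = cells_per_sample_per_type,
                 n_genes = as.integer(n_genes),
                 baseline_log_mean_range = baseline_log_mean_range,
                 nb_dispersion = nb_dispersion,
                 batch_log_sd = batch_log_sd,
                 signatures = signatures,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic multi-dataset cohort
#'
#' For each dataset `d` and gene `g`: baseline log-mean `base_g` ~
#' Uniform(baseline range), batch shift `batch_{d,g}` ~ Normal(0,
#' batch_log_sd). Samples are disease-labeled with the configured fraction;
#' each (sample, cell type) contributes a Poisson number of cells. The
#' count of gene `g` in cell `c` is negative binomial with mean
#' `exp(base_g + batch_{d,g} + effect)` and size `nb_dispersion`, where
#' `effect = log(2) * log2_effect_g` applies only when the cell's sample is
#' diseased and `g` belongs to the planted signature of the cell's type
#' (for multiplicative signatures the per-gene effects are jointly scaled
#' by a shared per-cell lognormal activation).
#'
#' @param config a [simulation_config()].
#' @return a `generated_cohort`: list with `datasets` (list of
#'   `expression_dataset`, ids "D1", "D2", ...) and `truth` (the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  panel <- paste0("g", seq_len(config$n_genes))
  base_log <- stats::runif(config$n_genes,
                           config$baseline_log_mean_range[1],
                           config$baseline_log_mean_range[2])
  sig_idx <- lapply(config$signatures, function(s)
    match(s$genes, panel))
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    did <- paste0("D", d)
    batch <- if (config$batch_log_sd > 0)
      stats::rnorm(config$n_genes, 0, config$batch_log_sd) else
      rep(0, config$n_genes)
    n_samp <- config$samples_per_dataset[d]
    samp_ids <- sprintf("%s_S%02d", did, seq_len(n_samp))
    disease <- stats::setNames(
      as.numeric(stats::runif(n_samp) < config$disease_fraction[d]),
      samp_ids)
    types <- config$cell_types_per_dataset[[d]]
    mu_base <- exp(base_log + batch)     # per-gene mean for this dataset
    rows <- list(); meta_type <- character(0); meta_samp <- character(0)
    for (s in seq_len(n_samp)) for (ct in types) {
      n_cells <- stats::rpois(1, config$cells_per_sample_per_type)
      if (n_cells == 0) next
      mu <- matrix(mu_base, nrow = n_cells, ncol = config$n_genes,
                   byrow = TRUE)
      sig <- config$signatures[[ct]]
      if (!is.null(sig) && disease[s] == 1) {
        fc <- 2^sig$log2_effects
        if (sig$interaction == "multiplicative") {
          act <- stats::rlnorm(n_cells, 0, 0.25)
          joint_fc <- 2^outer(act, sig$log2_effects)   # cells x sig genes
          mu[, sig_idx[[ct]]] <- mu[, sig_idx[[ct]], drop = FALSE] * joint_fc
        } else {
          mu[, sig_idx[[ct]]] <- sweep(mu[, sig_idx[[ct]], drop = FALSE],
                                       2, fc, `*`)
        }
      }
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                   size = config$nb_dispersion),
                    nrow = n_cells)
      rows[[length(rows) + 1L]] <- cnt
      meta_type <- c(meta_type, rep(ct, n_cells))
      meta_samp <- c(meta_samp, rep(samp_ids[s], n_cells))
    }
    for (ct in types) if (!ct %in% meta_type)
      warning(sprintf("dataset %s produced zero cells of type '%s'",
                      did, ct))
    if (!length(rows))
      stop_classed("sigtransfer_config",
                   "dataset %s produced no cells at all", did)
    counts <- do.call(rbind, rows)
    cell_ids <- sprintf("%s_C%05d", did, seq_len(nrow(counts)))
    datasets[[d]] <- expression_dataset(
      dataset_id = did, counts = counts, gene_ids = panel,
      cell_ids = cell_ids, cell_type = meta_type, sample_id = meta_samp,
      disease_state = disease)
  }
  structure(list(datasets = datasets, truth = config),
            class = "generated_cohort")
}

#' Look up the planted signature for a cell type
#'
#' @param cohort a `generated_cohort`.
#' @param cell_type cell-type label.
#' @return the planted [signature_spec()].
#' @export
truth_signature <- function(cohort, cell_type) {
  stopifnot(inherits(cohort, "generated_cohort"))
  sig <- cohort$truth$signatures[[cell_type]]
  if (is.null(sig))
    stop_classed("sigtransfer_lookup",
                 "no signature planted for cell type '%s'", cell_type)
  sig
}

#' Write / read a cohort as per-dataset directories plus a YAML config
#'
#' Each dataset goes to `<path>/<id>/` via [write_dataset()]; the
#' generating [simulation_config()] is stored as `<path>/config.yaml` so
#' that ground truth survives a round trip.
#'
#' @param cohort a `generated_cohort`.
#' @param path output directory.
#' @return `path` invisibly (`write_cohort`); a `generated_cohort`
#'   (`read_cohort`).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "generated_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ds in cohort$datasets)
    write_dataset(ds, file.path(path, ds$dataset_id))
  yaml::write_yaml(config_to_list(cohort$truth),
                   file.path(path, "config.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cfg <- config_from_list(yaml::read_yaml(file.path(path, "config.yaml")))
  ids <- paste0("D", seq_len(cfg$n_datasets))
  datasets <- lapply(ids, function(id)
    read_dataset(file.path(path, id), dataset_id = id))
  structure(list(datasets = datasets, truth = cfg),
            class = "generated_cohort")
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$signatures <- lapply(unname(out$signatures), unclass)
  out
}

config_from_list <- function(x) {
  sigs <- lapply(x$signatures, function(s)
    signature_spec(s$cell_type, unlist(s$genes), unlist(s$log2_effects),
                   s$interaction))
  simulation_config(
    n_datasets = x$n_datasets,
    samples_per_dataset = unlist(x$samples_per_dataset),
    disease_fraction = unlist(x$disease_fraction),
    cell_types_per_dataset = lapply(x$cell_types_per_dataset, unlist),
    cells_per_sample_per_type = x$cells_per_sample_per_type,
    n_genes = x$n_genes,
    baseline_log_mean_range = unlist(x$baseline_log_mean_range),
    nb_dispersion = x$nb_dispersion,
    batch_log_sd = x$batch_log_sd,
    signatures = sigs,
    seed = x$seed)
}
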