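#' Search configuration
#'
#' Settings for the evolutionary structure search with random sampling that
#' finds the best small formula models on a training slice.
#'
#' @param population_size candidates per generation.
#' @param generations number of generational refinement steps.
#' @param max_features structure cap, 1--3 genes.
#' @param n_models number of ranked models returned (the published protocol
#'   keeps 10 per run).
#' @param mutation_rates named probabilities for the move kinds
#'   `swap_gene`, `swap_operator`, `grow`, `shrink`; must sum to <= 1
#'   (renormalized when drawing).
#' @param candidate_gene_pool optional explicit gene subset; by default the
#'   `pool_size` most variable genes of the training slice.
#' @param pool_size cap on the default variance-ranked gene pool.
#' @param n_restarts_fit restarts per parameter fit during search.
#' @param fresh_fraction fraction of each new generation filled with fresh
#'   random structures (immigration) rather than mutants of the elites.
#' @param seed integer seed; searches are fully reproducible.
#' @return a `search_config`.
#' @export
search_config <- function(population_size = 64,
                          generations = 30,
                          max_features = 3,
                          n_models = 10,
                          mutation_rates = c(swap_gene = 0.4,
                                             swap_operator = 0.2,
                                             grow = 0.2, shrink = 0.2),
                          candidate_gene_pool = NULL,
                          pool_size = 500,
                          n_restarts_fit = 3,
                          fresh_fraction = 0.2,
                          seed = 1) {
  if (!max_features %in% 1:3)
    stop_classed("sigtransfer_config", "max_features must be 1, 2 or 3")
  if (n_models > population_size)
    stop_classed("sigtransfer_config",
                 "n_models cannot exceed population_size")
  need <- c("swap_gene", "swap_operator", "grow", "shrink")
  if (!all(need %in% names(mutation_rates)) || sum(mutation_rates) > 1 + 1e-9)
    stop_classed("sigtransfer_config",
                 "mutation_rates must name %s and sum to <= 1",
                 paste(need, collapse = ", "))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 max_features = as.integer(max_features),
                 n_models = as.integer(n_models),
                 mutation_rates = mutation_rates[need],
                 candidate_gene_pool = candidate_gene_pool,
                 pool_size = as.integer(pool_size),
                 n_restarts_fit = as.integer(n_restarts_fit),
                 fresh_fraction = fresh_fraction,
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Sample a random model structure
#'
#' Uniformly draws a feature count in `[1, max_features]` (capped by the
#' pool size), a set of distinct genes, and an operator for each internal
#' node. Parameters are left unfitted.
#'
#' @param genes character vector, the candidate gene pool.
#' @param config a [search_config()].
#' @param weights optional per-gene proposal weights (positive, aligned to
#'   `genes`); uniform when `NULL`. The search supplies weights derived
#'   from each gene's marginal label correlation, which concentrates
#'   proposals on informative genes while keeping full support.
#' @return an unfitted `formula_model`.
#' @export
sample_structure <- function(genes, config, weights = NULL) {
  if (!length(genes))
    stop_classed("sigtransfer_config", "empty gene pool")
  k <- sample.int(min(config$max_features, length(genes)), 1)
  feats <- sample_genes(genes, k, weights)
  ops <- sample(c("add", "multiply"), max(k - 1, 0), replace = TRUE)
  formula_model(feats, ops)
}

sample_genes <- function(genes, k, weights = NULL) {
  if (length(genes) == 1) return(rep(genes, min(k, 1)))
  sample(genes, k, prob = weights)
}

#' Mutate a model structure
#'
#' Applies exactly one structural move: swap one gene for an unused pool
#' gene, flip one operator, grow (attach a new gene through a new node), or
#' shrink (drop one leaf). A move kind with no legal application is
#' redrawn.
#'
#' @param model a `formula_model`.
#' @param genes candidate gene pool.
#' @param config a [search_config()] supplying `mutation_rates` and
#'   `max_features`.
#' @param weights optional per-gene proposal weights, as in
#'   [sample_structure()]; used when drawing the incoming gene for
#'   swap-gene and grow moves.
#' @return a mutated, unfitted `formula_model`.
#' @export
mutate_model <- function(model, genes, config, weights = NULL) {
  rates <- config$mutation_rates
  k <- length(model$features)
  unused <- setdiff(genes, model$features)
  legal <- c(swap_gene = length(unused) > 0,
             swap_operator = k > 1,
             grow = k < config$max_features && length(unused) > 0,
             shrink = k > 1)
  if (!any(legal)) return(model)
  # drawing only among legal kinds is equivalent to redraw-until-legal
  kinds <- names(rates)[legal[names(rates)]]
  move <- if (length(kinds) == 1) kinds else
    sample(kinds, 1, prob = rates[kinds])
  wu <- if (is.null(weights)) NULL else
    weights[match(unused, genes)]
  feats <- model$features; ops <- model$ops
  switch(move,
    swap_gene = {
      feats[sample.int(k, 1)] <- sample_genes(unused, 1, wu)
    },
    swap_operator = {
      j <- sample.int(k - 1, 1)
      ops[j] <- setdiff(c("add", "multiply"), ops[j])
    },
    grow = {
      feats <- c(feats, sample_genes(unused, 1, wu))
      ops <- c(ops, sample(c("add", "multiply"), 1))
    },
    shrink = {
      j <- sample.int(k, 1)
      feats <- feats[-j]
      ops <- ops[-min(max(j - 1, 1), length(ops))]
    })
  formula_model(feats, ops)
}

default_gene_pool <- function(slice, config) {
  pool <- config$candidate_gene_pool
  if (is.null(pool)) {
    v <- apply_col_var(slice$X)
    ord <- order(v, decreasing = TRUE)
    pool <- slice$gene_ids[ord[seq_len(min(config$pool_size, length(v)))]]
  } else {
    pool <- intersect(pool, slice$gene_ids)
  }
  if (!length(pool))
    stop_classed("sigtransfer_config", "gene pool is empty after filtering")
  pool
}

apply_col_var <- function(X) {
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  (Matrix::colSums(X^2) - n * mu^2) / max(n - 1, 1)
}

#' Evolutionary model search
#'
#' Finds the top `n_models` formula models for a training slice. Each
#' generation, every candidate structure is parameter-fitted
#' ([fit_parameters()]; fits are cached per structure), candidates are
#' ranked by training loss, the elite half survives, and the population is
#' refilled with mutants of the elites plus a fraction of fresh random
#' structures. Returned candidates are pairwise distinct in structure and
#' ranked by loss, then the complexity key, then the expression string.
#'
#' @param slice a `cell_type_slice` with both classes present.
#' @param config a [search_config()].
#' @return list of `model_candidate`s (each: `model`, `fit`,
#'   `train_metrics`), best first.
#' @export
search_models <- function(slice, config = search_config()) {
  stopifnot(inherits(slice, "cell_type_slice"))
  if (length(unique(slice$labels)) < 2L)
    stop_classed("sigtransfer_single_class",
                 "training slice must contain both classes")
  with_seed(config$seed, search_models_impl(slice, config))
}

search_models_impl <- function(slice, config) {
  pool <- default_gene_pool(slice, config)
  Xd <- as.matrix(slice$X[, pool, drop = FALSE])
  fit_slice <- list(X = Xd, labels = slice$labels)
  # proposal weights: marginal point-biserial correlation of each pool
  # gene with the labels, floored to keep every gene proposable
  u <- abs(suppressWarnings(as.numeric(
    stats::cor(Xd, slice$labels))))
  u[!is.finite(u)] <- 0
  w <- u + max(mean(u), 1e-8)
  w <- w / sum(w)
  cache <- new.env(parent = emptyenv())
  fit_cached <- function(model) {
    key <- structure_key(model)
    if (exists(key, envir = cache, inherits = FALSE))
      return(get(key, envir = cache, inherits = FALSE))
    fit <- fit_parameters(model, fit_slice,
                          n_restarts = config$n_restarts_fit,
                          seed = sample.int(.Machine$integer.max, 1))
    val <- list(model = fit$model, fit = fit, key = key)
    assign(key, val, envir = cache)
    val
  }
  rank_keys <- function(cands) {
    loss <- vapply(cands, function(c) c$fit$loss, numeric(1))
    cx <- t(vapply(cands, function(c) complexity(c$model), integer(2)))
    expr <- vapply(cands, function(c) model_expression(c$model), character(1))
    order(loss, cx[, 1], cx[, 2], expr)
  }
  pop <- lapply(seq_len(config$population_size), function(i)
    fit_cached(sample_structure(pool, config, w)))
  best_trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    pop <- pop[rank_keys(pop)]
    n_elite <- max(ceiling(config$population_size / 2), 1)
    elites <- pop[seq_len(min(n_elite, length(pop)))]
    n_fresh <- ceiling(config$fresh_fraction * config$population_size)
    n_mut <- config$population_size - length(elites) - n_fresh
    offspring <- c(
      lapply(seq_len(max(n_mut, 0)), function(i)
        fit_cached(mutate_model(
          elites[[((i - 1) %% length(elites)) + 1]]$model, pool, config,
          w))),
      lapply(seq_len(n_fresh), function(i)
        fit_cached(sample_structure(pool, config, w))))
    pop <- c(elites, offspring)
    best_trace[g] <- min(vapply(pop, function(c) c$fit$loss, numeric(1)))
  }
  pop <- pop[rank_keys(pop)]
  keys <- vapply(pop, `[[`, character(1), "key")
  pop <- pop[!duplicated(keys)]
  top <- pop[seq_len(min(config$n_models, length(pop)))]
  out <- lapply(top, function(c) {
    scores <- evaluate_model(c$model, Xd)
    structure(list(model = c$model, fit = c$fit,
                   train_metrics = metrics_report(slice$labels, scores)),
              class = "model_candidate")
  })
  attr(out, "best_loss_trace") <- best_trace
  out
}
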