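test_that("a one-gene pool always yields the single-leaf model", {
  cfg <- search_config(max_features = 3, seed = 1)
  set.seed(1)
  for (i in 1:20) {
    m <- sample_structure("gX", cfg)
    expect_identical(m$features, "gX")
    expect_length(m$ops, 0)
  }
})

test_that("structure sampling covers the whole small search space", {
  cfg <- search_config(max_features = 2, seed = 1)
  pool <- paste0("g", 1:5)
  set.seed(42)
  seen <- character(0)
  for (i in 1:10000) {
    m <- sample_structure(pool, cfg)
    key <- if (length(m$features) == 1) m$features else
      paste(sort(m$features), collapse = "+")
    seen <- union(seen, key)
  }
  singles <- pool
  pairs <- apply(combn(pool, 2), 2, paste, collapse = "+")
  expect_true(all(c(singles, pairs) %in% seen))
})

test_that("structure sampling is reproducible under a seed", {
  cfg <- search_config(seed = 9)
  pool <- paste0("g", 1:8)
  draw <- function() {
    set.seed(99)
    vapply(1:50, function(i) {
      m <- sample_structure(pool, cfg)
      paste(m$features, paste(m$ops, collapse = ""), collapse = "|")
    }, character(1))
  }
  expect_identical(draw(), draw())
})

test_that("mutation applies one legal move and respects the caps", {
  cfg <- search_config(max_features = 3, seed = 1)
  pool <- paste0("g", 1:6)
  set.seed(8)
  # shrink/swap-operator are illegal on a 1-feature model: redrawn moves
  # must still produce a valid model
  for (i in 1:30) {
    m <- mutate_model(formula_model("g1"), pool, cfg)
    expect_true(length(m$features) %in% 1:2)
    expect_s3_class(m, "formula_model")
  }
  # grow is illegal at max_features: no mutant may exceed the cap
  m3 <- formula_model(c("g1", "g2", "g3"), c("add", "multiply"))
  for (i in 1:30) {
    m <- mutate_model(m3, pool, cfg)
    expect_lte(length(m$features), 3)
    expect_equal(length(m$ops), max(length(m$features) - 1, 0))
  }
})

test_that("search equals exhaustive enumeration on single-gene structures", {
  sl <- make_gaussian_slice(n = 150, k = 6, n_signal = 1, effect = 1.5,
                            seed = 61)
  slice <- structure(list(dataset_id = "D1", cell_type = "T",
                          X = sl$X, labels = sl$labels,
                          gene_ids = colnames(sl$X)),
                     class = "cell_type_slice")
  cfg <- search_config(population_size = 12, generations = 4,
                       max_features = 1, n_models = 6, seed = 2)
  found <- search_models(slice, cfg)
  # brute-force oracle: fit each single-gene structure directly
  brute <- lapply(colnames(sl$X), function(g)
    fit_parameters(formula_model(g), sl, n_restarts = 3, seed = 7))
  best <- which.min(vapply(brute, `[[`, numeric(1), "loss"))
  expect_identical(found[[1]]$model$features, colnames(sl$X)[best])
  expect_equal(found[[1]]$fit$loss, brute[[best]]$loss, tolerance = 1e-4)
})

test_that("search matches exhaustive enumeration at two features", {
  sl <- make_gaussian_slice(n = 200, k = 6, n_signal = 2, effect = 1,
                            seed = 77)
  slice <- structure(list(dataset_id = "D1", cell_type = "T",
                          X = sl$X, labels = sl$labels,
                          gene_ids = colnames(sl$X)),
                     class = "cell_type_slice")
  cfg <- search_config(population_size = 60, generations = 20,
                       max_features = 2, n_models = 10, seed = 5)
  found <- search_models(slice, cfg)
  # enumerate every 1- and 2-feature structure (unordered for add,
  # both orders for multiply, whose node bias is order-sensitive)
  genes <- colnames(sl$X)
  structs <- c(lapply(genes, formula_model),
               apply(combn(genes, 2), 2, function(p)
                 formula_model(p, "add")),
               unlist(lapply(seq_len(ncol(combn(genes, 2))), function(i) {
                 p <- combn(genes, 2)[, i]
                 list(formula_model(p, "multiply"),
                      formula_model(rev(p), "multiply"))
               }), recursive = FALSE))
  losses <- vapply(structs, function(m)
    fit_parameters(m, sl, n_restarts = 3, seed = 13)$loss, numeric(1))
  expect_lt(found[[1]]$fit$loss, min(losses) + 1e-3)
})

test_that("the best training loss is non-increasing across generations", {
  sl <- make_gaussian_slice(n = 150, k = 5, n_signal = 1, effect = 1,
                            seed = 19)
  slice <- structure(list(dataset_id = "D1", cell_type = "T",
                          X = sl$X, labels = sl$labels,
                          gene_ids = colnames(sl$X)),
                     class = "cell_type_slice")
  found <- search_models(slice, search_config(population_size = 16,
                                              generations = 8, seed = 3))
  trace <- attr(found, "best_loss_trace")
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("returned candidates are structurally distinct and seeded", {
  sl <- make_gaussian_slice(n = 120, k = 5, n_signal = 1, effect = 1,
                            seed = 29)
  slice <- structure(list(dataset_id = "D1", cell_type = "T",
                          X = sl$X, labels = sl$labels,
                          gene_ids = colnames(sl$X)),
                     class = "cell_type_slice")
  cfg <- search_config(population_size = 16, generations = 5, seed = 4)
  f1 <- search_models(slice, cfg)
  f2 <- search_models(slice, cfg)
  keys <- vapply(f1, function(c) sigtransfer:::structure_key(c$model),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(lapply(f1, function(c) c$model),
                   lapply(f2, function(c) c$model))
})

test_that("search refuses single-class slices and empty pools", {
  sl <- make_gaussian_slice(n = 40, k = 3, seed = 1)
  slice <- structure(list(dataset_id = "D1", cell_type = "T",
                          X = sl$X, labels = rep(1, 40),
                          gene_ids = colnames(sl$X)),
                     class = "cell_type_slice")
  expect_error(search_models(slice, search_config()),
               class = "sigtransfer_single_class")
  slice$labels <- sl$labels
  expect_error(search_models(slice, search_config(
    candidate_gene_pool = "absent_gene")),
    class = "sigtransfer_config")
})
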