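make_typed_dataset <- function(id, types, n_per_type = 2) {
  n <- length(types) * n_per_type
  make_tiny_dataset(id, matrix(rpois(n * 2, 3) + 1, n, 2),
                    cell_type = rep(types, each = n_per_type),
                    sample_id = rep("s1", n),
                    disease_state = c(s1 = 0))
}

test_that("shared cell types map to the datasets containing them", {
  set.seed(1)
  d1 <- make_typed_dataset("D1", c("IgA plasma", "Goblet"))
  d2 <- make_typed_dataset("D2", c("IgA plasma", "Myofibroblast"))
  d3 <- make_typed_dataset("D3", c("IgA plasma", "Goblet"))
  d4 <- make_typed_dataset("D4", c("IgA plasma", "CD8 T"))
  shared <- shared_cell_types(list(d1, d2, d3, d4))
  # exactly one type common to all four datasets
  expect_identical(shared[["IgA plasma"]], c("D1", "D2", "D3", "D4"))
  expect_identical(shared[["Goblet"]], c("D1", "D3"))
  expect_identical(shared[["CD8 T"]], "D4")
  # fully disjoint type sets leave nothing transferable
  da <- make_typed_dataset("Da", "A"); db <- make_typed_dataset("Db", "B")
  sizes <- lengths(shared_cell_types(list(da, db)))
  expect_true(all(sizes == 1))
})

test_that("uc_fraction counts disease cells of a type", {
  counts <- matrix(1, 4, 2)
  ds <- make_tiny_dataset("D1", counts,
                          cell_type = rep("T", 4),
                          sample_id = c("s1", "s2", "s3", "s4"),
                          disease_state = c(s1 = 1, s2 = 0, s3 = 0, s4 = 0))
  expect_equal(uc_fraction(ds, "T"), 0.25)
  ds0 <- make_tiny_dataset("D2", counts, cell_type = rep("T", 4),
                           sample_id = rep("s1", 4),
                           disease_state = c(s1 = 0))
  expect_equal(uc_fraction(ds0, "T"), 0)
  expect_error(uc_fraction(ds, "missing"), class = "sigtransfer_lookup")
})

test_that("the realized disease fraction tracks the configured rate", {
  cfg <- simulation_config(
    n_datasets = 2, samples_per_dataset = 60, disease_fraction = 0.28,
    cell_types_per_dataset = list("T", "T"),
    cells_per_sample_per_type = 20, n_genes = 5, seed = 41)
  coh <- generate_cohort(cfg)
  f <- uc_fraction(coh$datasets[[1]], "T")
  se <- sqrt(0.28 * 0.72 / 60)
  expect_lt(abs(f - 0.28), 3 * se)
})

test_that("selection filters on the AUC gap then prefers simplicity", {
  cands <- list(
    fake_candidate(c("g1", "g2", "g3"), c("add", "add"), 0.90),
    fake_candidate(c("g1", "g2"), "add", 0.92),
    fake_candidate(c("g4", "g5"), "multiply", 0.92),
    fake_candidate("g6", character(0), 0.95))
  # candidate 4 has a 0.15 gap: filtered despite being simplest
  sel <- select_model(cands, c(0.88, 0.88, 0.88, 0.80))
  expect_equal(sel$index, 2)   # fewest features among survivors, additive
  expect_false(sel$fallback)
  # additive preferred over multiply at equal feature count and score
  sel2 <- select_model(cands[2:3], c(0.90, 0.90))
  expect_equal(sel2$index, 1)
  # no survivor: fall back to the highest transfer score with a flag
  sel3 <- select_model(cands, c(0.5, 0.55, 0.4, 0.45))
  expect_true(sel3$fallback)
  expect_equal(sel3$index, 2)
  expect_error(select_model(list(), numeric(0)),
               class = "sigtransfer_selection")
})

test_that("dominant features are the two most frequent genes", {
  mk <- function(features) fake_candidate(features,
    rep("add", max(length(features) - 1, 0)), 0.9)
  cands <- c(rep(list(mk(c("A", "B", "C"))), 2),
             rep(list(mk(c("A", "B"))), 3),
             rep(list(mk("A")), 2))
  # A in 7 models, B in 5, C in 2
  expect_identical(dominant_features(cands), c("A", "B"))
  # single recurring gene: second slot empty
  expect_identical(dominant_features(rep(list(mk("G")), 4)),
                   c("G", NA_character_))
  # ties broken lexicographically
  tie <- c(rep(list(mk(c("B", "A"))), 5))
  expect_identical(dominant_features(tie), c("A", "B"))
})

test_that("summary rows reproduce the published table formatting", {
  rec <- data.frame(
    train_id = "D1", test_id = "D2", cell_type = "Arterial Capillary",
    dominant_feature_1 = "RPL39", dominant_feature_2 = "PLAT",
    pr_auc_train = 0.95, pr_auc_test = 0.94,
    score = transfer_score(0.95, 0.94),
    n_train_cells = 1814L, n_test_cells = 559L,
    uc_fraction_train = 0.28, uc_fraction_test = 0.22,
    selection_fallback = FALSE, stringsAsFactors = FALSE)
  df <- summarize_transfers(rec)
  expect_identical(df$`PR AUC`, "0.95/0.94")
  expect_identical(df$Score, "0.94")        # 0.935 rounded half-up
  expect_identical(df$Count, "1814/559")
  expect_identical(df$`UC Fraction`, "28%/22%")
  expect_identical(df$`Dominant Features`, "RPL39, PLAT")
  # empty record list: header-only file
  f <- tempfile(fileext = ".tsv")
  summarize_transfers(rec[0, ], f)
  expect_identical(readLines(f),
                   paste("Training ID", "Test ID", "Cell Type",
                         "Dominant Features", "PR AUC", "Score", "Count",
                         "UC Fraction", sep = "\t"))
})

test_that("summary rows sort by training dataset then descending score", {
  rec <- do.call(rbind, lapply(1:3, function(i) {
    r <- data.frame(train_id = c("D2", "D1", "D1")[i],
                    test_id = "Dx", cell_type = paste0("T", i),
                    dominant_feature_1 = "A", dominant_feature_2 = "B",
                    pr_auc_train = c(0.9, 0.7, 0.95)[i],
                    pr_auc_test = c(0.9, 0.7, 0.93)[i],
                    score = 0, n_train_cells = 1L, n_test_cells = 1L,
                    uc_fraction_train = 0.5, uc_fraction_test = 0.5,
                    selection_fallback = FALSE)
    r$score <- transfer_score(r$pr_auc_train, r$pr_auc_test)
    r
  }))
  df <- summarize_transfers(rec)
  expect_identical(df$`Cell Type`, c("T3", "T2", "T1"))
})

test_that("transfer records are internally consistent and deterministic", {
  cfg <- recovery_config(seed = 71, samples_per_dataset = 10,
                         cells_per_sample_per_type = 15, n_genes = 30)
  coh <- generate_cohort(cfg)
  datasets <- lapply(coh$datasets, normalize_log1p)
  scfg <- search_config(population_size = 16, generations = 4, seed = 5,
                        n_restarts_fit = 2)
  rec <- run_transfer(datasets, scfg)
  # both transfer directions exist for the shared type
  expect_setequal(paste(rec$train_id, rec$test_id),
                  c("D1 D2", "D2 D1"))
  # the score column is the transfer score of the row's own AUCs
  expect_equal(rec$score,
               transfer_score(rec$pr_auc_train, rec$pr_auc_test),
               tolerance = 1e-12)
  # end-to-end seeded determinism, byte for byte
  f1 <- tempfile(); f2 <- tempfile()
  summarize_transfers(rec, f1)
  summarize_transfers(run_transfer(lapply(generate_cohort(cfg)$datasets,
                                          normalize_log1p),
                                   scfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("transfers without shared cell types warn and return nothing", {
  set.seed(2)
  da <- make_typed_dataset("Da", "A"); db <- make_typed_dataset("Db", "B")
  da <- normalize_log1p(da); db <- normalize_log1p(db)
  expect_warning(rec <- run_transfer(list(da, db)), "no cell types")
  expect_equal(nrow(rec), 0)
})
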