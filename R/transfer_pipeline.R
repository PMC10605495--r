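#' Cell types shared between datasets
#'
#' Maps every observed cell type to the set of dataset ids containing at
#' least one cell of it. Transfer pairs are generated only for types shared
#' by two or more datasets.
#'
#' @param datasets list of `expression_dataset`s.
#' @return named list: cell type -> character vector of dataset ids.
#' @export
shared_cell_types <- function(datasets) {
  if (length(datasets) < 2)
    stop_classed("sigtransfer_config", "need at least 2 datasets")
  types <- sort(unique(unlist(lapply(datasets, function(d)
    unique(d$cell_type)))))
  out <- lapply(types, function(ct)
    unlist(lapply(datasets, function(d)
      if (ct %in% d$cell_type) d$dataset_id else NULL)))
  stats::setNames(out, types)
}

#' Disease fraction of a cell type in a dataset
#'
#' Fraction of the type's cells whose sample of origin carries a disease
#' label — the "UC Fraction" column of the transfer report.
#'
#' @param ds an `expression_dataset`.
#' @param cell_type cell-type label.
#' @return fraction in \[0, 1\].
#' @export
uc_fraction <- function(ds, cell_type) {
  idx <- which(ds$cell_type == cell_type)
  if (!length(idx))
    stop_classed("sigtransfer_lookup", "cell type '%s' absent from %s",
                 cell_type, ds$dataset_id)
  mean(ds$disease_state[ds$sample_id[idx]])
}

#' Model-selection criteria
#'
#' The published selection protocol: discard candidates whose training and
#' test PR AUCs differ by the gap threshold or more (overfitting guard),
#' then among the survivors prefer fewer features, then purely additive
#' structures, then the higher transfer score.
#'
#' @param max_auc_gap maximum absolute PR AUC difference between training
#'   and test (default 0.10); with `relative_gap = TRUE` the gap is
#'   measured relative to the training AUC instead.
#' @param prefer_fewer_features,prefer_additive toggles for the secondary
#'   ranking rules.
#' @param relative_gap interpret `max_auc_gap` as a relative difference.
#' @return a `selection_criteria`.
#' @export
selection_criteria <- function(max_auc_gap = 0.10,
                               prefer_fewer_features = TRUE,
                               prefer_additive = TRUE,
                               relative_gap = FALSE) {
  if (max_auc_gap <= 0 || max_auc_gap > 1)
    stop_classed("sigtransfer_config", "max_auc_gap must be in (0, 1]")
  structure(list(max_auc_gap = max_auc_gap,
                 prefer_fewer_features = isTRUE(prefer_fewer_features),
                 prefer_additive = isTRUE(prefer_additive),
                 relative_gap = isTRUE(relative_gap)),
            class = "selection_criteria")
}

#' Select the reported model among evaluated candidates
#'
#' @param candidates list of `model_candidate`s from [search_models()].
#' @param test_pr_auc numeric vector, each candidate's PR AUC on the test
#'   slice (NA for candidates that could not be evaluated there).
#' @param criteria a [selection_criteria()].
#' @return list: `index` of the chosen candidate, `fallback` flag (TRUE
#'   when no candidate survived the gap filter and the highest-score one
#'   was taken instead).
#' @export
select_model <- function(candidates, test_pr_auc,
                         criteria = selection_criteria()) {
  if (!length(candidates))
    stop_classed("sigtransfer_selection", "no candidates to select from")
  stopifnot(length(test_pr_auc) == length(candidates))
  train <- vapply(candidates, function(c) c$train_metrics$pr_auc, numeric(1))
  ok <- !is.na(test_pr_auc)
  if (!any(ok))
    stop_classed("sigtransfer_selection",
                 "no candidate could be evaluated on the test slice")
  gap <- abs(train - test_pr_auc)
  if (criteria$relative_gap) gap <- gap / pmax(train, 1e-12)
  score <- transfer_score(train, ifelse(ok, test_pr_auc, 0))
  surv <- which(ok & gap < criteria$max_auc_gap)
  fallback <- length(surv) == 0
  if (fallback) {
    # no candidate passed the overfitting guard: report the best raw score
    cand <- which(ok)
    return(list(index = cand[which.max(score[cand])], fallback = TRUE))
  }
  nf <- vapply(candidates, function(c) complexity(c$model)[1], integer(1))
  addv <- vapply(candidates, function(c)
    as.integer(any(c$model$ops == "multiply")), integer(1))
  expr <- vapply(candidates, function(c) model_expression(c$model),
                 character(1))
  keys <- list(if (criteria$prefer_fewer_features) nf[surv] else
                 rep(0L, length(surv)),
               if (criteria$prefer_additive) addv[surv] else
                 rep(0L, length(surv)),
               -score[surv],
               expr[surv])
  idx <- surv[do.call(order, keys)][1]
  list(index = idx, fallback = fallback)
}

#' Dominant features across a run's candidate models
#'
#' Counts in how many of the candidate models each gene appears (presence
#' per model, not leaf multiplicity) and returns the top two, ties broken
#' lexicographically. The second slot is `NA` when only one gene occurs.
#'
#' @param candidates list of `model_candidate`s.
#' @return character vector of length 2.
#' @export
dominant_features <- function(candidates) {
  if (!length(candidates))
    stop_classed("sigtransfer_selection", "no candidates")
  feats <- unlist(lapply(candidates, function(c) unique(c$model$features)))
  tab <- table(feats)
  ord <- order(-as.vector(tab), names(tab))
  top <- names(tab)[ord]
  c(top[1], if (length(top) >= 2) top[2] else NA_character_)
}

#' Run the full cross-dataset transfer analysis
#'
#' For every cell type shared between two or more datasets and every
#' dataset containing both classes of that type, a model search is run on
#' the training slice; each of the returned candidates is then evaluated on
#' the same cell type in every other dataset sharing it (features aligned
#' by gene symbol; candidates with genes absent from the test panel are
#' skipped), the selection criteria pick the reported model, and one
#' transfer record per (train, test, type) is emitted. Deterministic under
#' the search seed: per-search seeds are derived from `config$seed` and the
#' (cell type, train dataset) run index.
#'
#' @param datasets list of normalized `expression_dataset`s.
#' @param config a [search_config()].
#' @param criteria a [selection_criteria()].
#' @param positive_class positive-class polarity, see [slice_cell_type()].
#' @param train_ids optional character vector restricting which datasets
#'   are used for training (all by default); test datasets are unaffected.
#' @return a data.frame of transfer records (one row per train/test/type)
#'   with an attached list of selected models (`attr(., "models")`, keyed
#'   `train:test:type`) and a list of skipped pairs with reasons
#'   (`attr(., "skipped")`).
#' @export
run_transfer <- function(datasets, config = search_config(),
                         criteria = selection_criteria(),
                         positive_class = "disease",
                         train_ids = NULL) {
  shared <- shared_cell_types(datasets)
  shared <- shared[vapply(shared, length, integer(1)) >= 2]
  if (!length(shared)) {
    warning("no cell types are shared between datasets")
    return(empty_records())
  }
  by_id <- stats::setNames(datasets,
                           vapply(datasets, `[[`, character(1), "dataset_id"))
  records <- list(); models <- list(); skipped <- list()
  run_idx <- 0L
  for (ct in names(shared)) {
    for (train_id in shared[[ct]]) {
      run_idx <- run_idx + 1L
      if (!is.null(train_ids) && !train_id %in% train_ids) next
      train_slice <- slice_cell_type(by_id[[train_id]], ct,
                                     positive_class = positive_class)
      if (length(unique(train_slice$labels)) < 2L) {
        skipped[[length(skipped) + 1L]] <- list(
          train = train_id, cell_type = ct,
          reason = "single-class training slice")
        next
      }
      cfg <- config
      cfg$seed <- (config$seed + 7919L * run_idx) %% .Machine$integer.max
      cands <- search_models(train_slice, cfg)
      for (test_id in setdiff(shared[[ct]], train_id)) {
        test_slice <- slice_cell_type(by_id[[test_id]], ct,
                                      positive_class = positive_class)
        if (length(unique(test_slice$labels)) < 2L) {
          skipped[[length(skipped) + 1L]] <- list(
            train = train_id, test = test_id, cell_type = ct,
            reason = "single-class test slice")
          next
        }
        Xt <- as.matrix(test_slice$X)
        test_auc <- vapply(cands, function(c) {
          if (!all(c$model$features %in% colnames(Xt)))
            return(NA_real_)
          pr_auc(test_slice$labels, evaluate_model(c$model, Xt))
        }, numeric(1))
        sel <- select_model(cands, test_auc, criteria)
        chosen <- cands[[sel$index]]
        a <- chosen$train_metrics$pr_auc
        b <- test_auc[sel$index]
        key <- paste(train_id, test_id, ct, sep = ":")
        models[[key]] <- chosen$model
        records[[length(records) + 1L]] <- data.frame(
          train_id = train_id, test_id = test_id, cell_type = ct,
          dominant_feature_1 = dominant_features(cands)[1],
          dominant_feature_2 = dominant_features(cands)[2],
          pr_auc_train = a, pr_auc_test = b,
          score = transfer_score(a, b),
          n_train_cells = length(train_slice$labels),
          n_test_cells = length(test_slice$labels),
          uc_fraction_train = uc_fraction(by_id[[train_id]], ct),
          uc_fraction_test = uc_fraction(by_id[[test_id]], ct),
          selection_fallback = sel$fallback,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(records)) do.call(rbind, records) else empty_records()
  attr(out, "models") <- models
  attr(out, "skipped") <- skipped
  class(out) <- c("transfer_records", class(out))
  out
}

empty_records <- function() {
  data.frame(train_id = character(0), test_id = character(0),
             cell_type = character(0),
             dominant_feature_1 = character(0),
             dominant_feature_2 = character(0),
             pr_auc_train = numeric(0), pr_auc_test = numeric(0),
             score = numeric(0),
             n_train_cells = integer(0), n_test_cells = integer(0),
             uc_fraction_train = numeric(0), uc_fraction_test = numeric(0),
             selection_fallback = logical(0), stringsAsFactors = FALSE)
}

#' Format transfer records as a publication-style summary table
#'
#' One row per transfer with the columns `Training ID`, `Test ID`,
#' `Cell Type`, `Dominant Features`, `PR AUC` (train/test at 2 decimals,
#' "/"-joined), `Score` (2 decimals, half-up), `Count` (train/test cell
#' counts) and `UC Fraction` (percentages). Rows are sorted by Training ID,
#' then Score descending.
#'
#' @param records a data.frame from [run_transfer()].
#' @param file optional path; when given the table is written as TSV
#'   (UTF-8, LF line ends) and the path returned invisibly.
#' @return the formatted data.frame (or the path when `file` is set).
#' @export
summarize_transfers <- function(records, file = NULL) {
  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  pct <- function(x) sprintf("%.0f%%", round_half_up(100 * x, 0))
  if (nrow(records)) {
    df <- data.frame(
      `Training ID` = records$train_id,
      `Test ID` = records$test_id,
      `Cell Type` = records$cell_type,
      `Dominant Features` = ifelse(
        is.na(records$dominant_feature_2), records$dominant_feature_1,
        paste(records$dominant_feature_1, records$dominant_feature_2,
              sep = ", ")),
      `PR AUC` = paste(fmt2(records$pr_auc_train),
                       fmt2(records$pr_auc_test), sep = "/"),
      Score = fmt2(records$score),
      Count = paste(records$n_train_cells, records$n_test_cells, sep = "/"),
      `UC Fraction` = paste(pct(records$uc_fraction_train),
                            pct(records$uc_fraction_test), sep = "/"),
      check.names = FALSE, stringsAsFactors = FALSE)
    df <- df[order(df$`Training ID`, -round_half_up(records$score, 2),
                   df$`Cell Type`), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(`Training ID` = character(0), `Test ID` = character(0),
                     `Cell Type` = character(0),
                     `Dominant Features` = character(0),
                     `PR AUC` = character(0), Score = character(0),
                     Count = character(0), `UC Fraction` = character(0),
                     check.names = FALSE)
  }
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(names(df), collapse = "\t"),
                 if (nrow(df)) do.call(paste,
                                       c(unname(as.list(df)), sep = "\t"))),
               con, sep = "\n")
    return(invisible(file))
  }
  df
}
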