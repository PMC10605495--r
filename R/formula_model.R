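#' Symbolic gene-signature classifier models
#'
#' A `formula_model` is a small interpretable classifier mapping the
#' normalized expression of 1--3 genes to a disease probability. The model
#' is a binary expression tree over \{add, multiply\} with the genes at the
#' leaves and a logistic output link. Trees are kept in canonical left-deep
#' form: features `f1..fk` are combined pairwise by operators `o1..o_{k-1}`,
#'
#'   v1 = w1*f1;  vj = vj-1 (op) (wj*fj + bj-1);  p = logistic(vk + b0)
#'
#' so each leaf carries a weight, each internal node a bias (attached to its
#' right operand), plus one output bias. This class expresses the published
#' three-gene forms such as "(add two genes) then multiply a third" and fully
#' additive signatures, with at most 2*k parameters.
#'
#' @param features character vector of 1--3 distinct gene identifiers
#'   (length 0 is permitted as the degenerate bias-only model).
#' @param ops character vector of operators, one per internal node
#'   (`length(features) - 1` entries), each `"add"` or `"multiply"`.
#' @param params optional numeric parameter vector of length
#'   `2 * length(features)`: leaf weights, node biases, output bias.
#'   `NULL` marks an unfitted structure.
#' @return an object of class `formula_model`.
#' @examples
#' m <- formula_model(c("LYZ", "FABP1", "LGALS4"), c("add", "multiply"))
#' model_expression(m)
#' @export
formula_model <- function(features, ops = character(0), params = NULL) {
  features <- as.character(features)
  k <- length(features)
  if (k > 3)
    stop_classed("sigtransfer_invalid_model",
                 "a formula model may use at most 3 features, got %d", k)
  if (anyDuplicated(features))
    stop_classed("sigtransfer_invalid_model", "features must be distinct")
  ops <- as.character(ops)
  if (length(ops) != max(k - 1L, 0L))
    stop_classed("sigtransfer_invalid_model",
                 "need %d operator(s) for %d features, got %d",
                 max(k - 1L, 0L), k, length(ops))
  if (!all(ops %in% c("add", "multiply")))
    stop_classed("sigtransfer_invalid_model",
                 "operators must be 'add' or 'multiply'")
  if (!is.null(params)) {
    params <- as.numeric(params)
    if (length(params) != n_params(k) || !all(is.finite(params)))
      stop_classed("sigtransfer_invalid_model",
                   "params must be %d finite values", n_params(k))
  }
  structure(list(features = features, ops = ops, params = params),
            class = "formula_model")
}

n_params <- function(k) if (k == 0L) 1L else 2L * k

#' @export
print.formula_model <- function(x, ...) {
  cat("<formula_model> ", model_expression(x), "\n", sep = "")
  invisible(x)
}

#' Structural complexity of a model
#'
#' Lexicographic complexity key: number of distinct features, then number of
#' internal nodes. Used to rank equal-loss candidates and to prefer simpler
#' signatures during selection.
#'
#' @param model a `formula_model`.
#' @return integer vector `c(n_features, n_internal_nodes)`.
#' @export
complexity <- function(model) {
  stopifnot(inherits(model, "formula_model"))
  c(length(model$features), length(model$ops))
}

# Canonical structure identity (ignores parameters). Purely additive chains
# are permutation-invariant in their features, so those are sorted; chains
# containing a multiply node are order-sensitive (the node bias sits on the
# right operand) and keep their feature order. Used for fit caching and
# candidate de-duplication.
structure_key <- function(model) {
  feats <- model$features
  if (all(model$ops == "add")) feats <- sort(feats)
  paste(paste(feats, collapse = ","),
        paste(model$ops, collapse = ","), sep = "|")
}

split_params <- function(model) {
  k <- length(model$features)
  p <- model$params
  if (is.null(p)) p <- rep(0, n_params(k))
  if (k == 0L) return(list(w = numeric(0), b = numeric(0), bout = p[1]))
  list(w = p[seq_len(k)],
       b = if (k > 1) p[k + seq_len(k - 1L)] else numeric(0),
       bout = p[2L * k])
}

# Linear predictor of the tree for an aligned feature matrix (cells x k).
forward_z <- function(features, ops, par, X) {
  k <- length(features)
  if (k == 0L) return(rep(par[1], nrow(X)))
  w <- par[seq_len(k)]
  b <- if (k > 1) par[k + seq_len(k - 1L)] else numeric(0)
  bout <- par[2L * k]
  v <- X[, 1L] * w[1L]
  if (k > 1) for (j in 2:k) {
    r <- X[, j] * w[j] + b[j - 1L]
    v <- if (ops[j - 1L] == "add") v + r else v * r
  }
  v + bout
}

#' Evaluate a formula model
#'
#' Computes the per-cell disease probability `logistic(tree + bias)`.
#' Probabilities are clipped to lie strictly inside (0, 1).
#'
#' @param model a fitted `formula_model`.
#' @param X numeric matrix of normalized expression with named columns
#'   covering `model$features` (extra columns are ignored).
#' @return numeric vector of probabilities, one per row of X.
#' @export
evaluate_model <- function(model, X) {
  stopifnot(inherits(model, "formula_model"))
  if (is.null(model$params))
    stop_classed("sigtransfer_unfitted", "model has no fitted parameters")
  X <- as.matrix(X)
  k <- length(model$features)
  if (k > 0) {
    miss <- setdiff(model$features, colnames(X))
    if (length(miss))
      stop_classed("sigtransfer_alignment",
                   "feature column(s) missing from X: %s",
                   paste(miss, collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  }
  z <- forward_z(model$features, model$ops, model$params, X)
  p <- stats::plogis(z)
  unname(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' @rdname evaluate_model
#' @param object a `formula_model`.
#' @param newdata feature matrix, as `X` in `evaluate_model`.
#' @param ... unused.
#' @export
predict.formula_model <- function(object, newdata, ...) {
  evaluate_model(object, newdata)
}

# Mean binary cross-entropy (nats) and its analytic gradient for the chain
# tree. Numerically stable log(1+exp(.)) form; non-finite values (possible
# under runaway multiply nodes) are mapped to a large penalty.
bce_objective <- function(features, ops, X, y) {
  k <- length(features)
  n <- length(y)
  fn <- function(par) {
    z <- forward_z(features, ops, par, X)
    if (!all(is.finite(z))) return(1e10)
    loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
    if (!is.finite(loss)) 1e10 else loss
  }
  gr <- function(par) {
    if (k == 0L) {
      z <- rep(par[1], n)
      return(mean(stats::plogis(z) - y))
    }
    w <- par[seq_len(k)]
    b <- if (k > 1) par[k + seq_len(k - 1L)] else numeric(0)
    # forward pass, keeping node values
    v <- vector("list", k)
    r <- vector("list", k)
    v[[1]] <- X[, 1L] * w[1L]
    if (k > 1) for (j in 2:k) {
      r[[j]] <- X[, j] * w[j] + b[j - 1L]
      v[[j]] <- if (ops[j - 1L] == "add") v[[j - 1L]] + r[[j]] else
        v[[j - 1L]] * r[[j]]
    }
    z <- v[[k]] + par[2L * k]
    if (!all(is.finite(z))) return(rep(0, length(par)))
    dz <- (stats::plogis(z) - y) / n      # dL/dz per cell
    gw <- numeric(k); gb <- numeric(max(k - 1L, 0L))
    gv <- dz                              # dL/dv_j, backwards
    if (k > 1) for (j in k:2) {
      if (ops[j - 1L] == "add") {
        grj <- gv
      } else {
        grj <- gv * v[[j - 1L]]
        gv <- gv * r[[j]]
      }
      gw[j] <- sum(grj * X[, j])
      gb[j - 1L] <- sum(grj)
    }
    gw[1L] <- sum(gv * X[, 1L])
    c(gw, gb, sum(dz))
  }
  list(fn = fn, gr = gr)
}

#' Fit model parameters by penalized-free maximum likelihood
#'
#' Minimizes mean binary cross-entropy over the model's parameters with
#' multi-restart BFGS. Restarts are initialized from a scaled standard
#' normal; a bias-only start (all weights zero, output bias at the logit of
#' the class prevalence) is always included, so the returned loss never
#' exceeds the intercept-only loss.
#'
#' @param model a `formula_model` (parameters, if present, are ignored).
#' @param slice a `cell_type_slice` (see [slice_cell_type()]), or any list
#'   with elements `X` (cells x genes matrix, named columns) and `labels`
#'   (binary vector).
#' @param n_restarts number of random restarts in addition to the bias-only
#'   start.
#' @param seed integer seed controlling restart initialization.
#' @return a `fit_result` list: `loss`, `n_restarts_used`, `converged`,
#'   `params`, and `model` (the input structure carrying the fitted params).
#' @export
fit_parameters <- function(model, slice, n_restarts = 5, seed = 1) {
  stopifnot(inherits(model, "formula_model"))
  X <- as.matrix(slice$X)
  y <- as.numeric(slice$labels)
  if (!all(y %in% c(0, 1)))
    stop_classed("sigtransfer_labels", "labels must be binary 0/1")
  k <- length(model$features)
  if (k > 0) {
    if (length(unique(y)) < 2L)
      stop_classed("sigtransfer_single_class",
        "labels contain a single class; exclude this slice from training")
    miss <- setdiff(model$features, colnames(X))
    if (length(miss))
      stop_classed("sigtransfer_alignment",
                   "feature column(s) missing from slice: %s",
                   paste(miss, collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  } else {
    X <- matrix(0, nrow = length(y), ncol = 0)
  }
  obj <- bce_objective(model$features, model$ops, X, y)
  np <- n_params(k)
  prev <- mean(y)
  bias_start <- rep(0, np)
  bias_start[np] <- stats::qlogis(min(max(prev, 1e-12), 1 - 1e-12))
  starts <- with_seed(seed, {
    c(list(bias_start),
      lapply(seq_len(n_restarts), function(i) stats::rnorm(np, 0, 0.5)))
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = 150, reltol = 1e-7)),
      error = function(e) NULL)
    cand <- list()
    if (!is.null(res))
      cand <- list(list(par = res$par, value = res$value,
                        conv = res$convergence == 0))
    # the start itself is a candidate (guards optim moving uphill on 1e10s)
    cand <- c(cand, list(list(par = s, value = obj$fn(s), conv = TRUE)))
    for (cc in cand)
      if (is.null(best) || cc$value < best$value) best <- cc
  }
  fitted <- model
  fitted$params <- best$par
  structure(list(loss = best$value,
                 n_restarts_used = n_restarts,
                 converged = isTRUE(best$conv),
                 params = best$par,
                 model = fitted),
            class = "fit_result")
}

#' Human-readable expression string
#'
#' Renders the model as a logistic formula, e.g.
#' `logistic(((a*LYZ + b*FABP1 + c) * (d*LGALS4 + e)) + f)`; fitted
#' parameter values are shown rounded to 3 decimals, unfitted structures use
#' letters.
#'
#' @param model a `formula_model`.
#' @param digits decimals used for fitted parameter values.
#' @return a character scalar.
#' @export
model_expression <- function(model, digits = 3) {
  k <- length(model$features)
  np <- n_params(k)
  lab <- if (is.null(model$params)) letters[seq_len(np)] else
    as.character(round(model$params, digits))
  if (k == 0L) return(sprintf("logistic(%s)", lab[np]))
  term <- function(j) sprintf("%s*%s", lab[j], model$features[j])
  e <- term(1L)
  if (k > 1) for (j in 2:k) {
    rhs <- sprintf("%s + %s", term(j), lab[k + j - 1L])
    e <- if (model$ops[j - 1L] == "add")
      sprintf("(%s + %s)", e, rhs) else sprintf("(%s * (%s))", e, rhs)
  }
  sprintf("logistic(%s + %s)", e, lab[np])
}

#' Serialize a formula model to JSON
#'
#' The schema records the feature list, the nested operator tree, the
#' parameter vector, the rendered expression string and optional metadata
#' (training dataset, cell type, seed). [model_from_json()] inverts it
#' exactly on structure and parameters.
#'
#' @param model a `formula_model`.
#' @param meta optional named list of metadata stored verbatim.
#' @return JSON text (character scalar).
#' @export
model_to_json <- function(model, meta = NULL) {
  stopifnot(inherits(model, "formula_model"))
  tree <- if (length(model$features) == 0L) NULL else
    Reduce(function(acc, j) list(op = model$ops[j - 1L], left = acc,
                                 right = list(leaf = model$features[j])),
           x = seq_along(model$features)[-1],
           init = list(leaf = model$features[1L]))
  jsonlite::toJSON(list(features = I(model$features),
                        tree = tree,
                        params = I(model$params),
                        expression = model_expression(model),
                        meta = meta),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

flatten_tree <- function(node) {
  if (!is.null(node$leaf)) return(list(features = as.character(node$leaf),
                                       ops = character(0)))
  l <- flatten_tree(node$left)
  if (is.null(node$right$leaf))
    stop_classed("sigtransfer_parse", "tree is not in left-deep form")
  list(features = c(l$features, as.character(node$right$leaf)),
       ops = c(l$ops, as.character(node$op)))
}

#' @rdname model_to_json
#' @param txt JSON text produced by `model_to_json`.
#' @export
model_from_json <- function(txt) {
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop_classed("sigtransfer_parse",
                                 "malformed model JSON: %s",
                                 conditionMessage(e)))
  feats <- as.character(unlist(obj$features))
  if (is.null(obj$tree)) {
    m <- formula_model(character(0), params = unlist(obj$params))
  } else {
    fl <- flatten_tree(obj$tree)
    if (!identical(fl$features, feats))
      stop_classed("sigtransfer_parse",
                   "tree leaves disagree with the feature list")
    m <- formula_model(fl$features, fl$ops,
                       params = if (is.null(obj$params)) NULL else
                         unlist(obj$params))
  }
  attr(m, "meta") <- obj$meta
  m
}
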