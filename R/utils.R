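#' Round half away from zero to a fixed number of decimals
#'
#' Display rounding used for tabular reports: 0.935 becomes 0.94 at two
#' decimals, unlike [base::round()]'s round-half-even. A tiny epsilon guards
#' against binary representation error on exact half values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Evaluate an expression with a temporary RNG seed, restoring prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Coerce to column-sparse general form. Matrix::Matrix() first, so the
# Matrix namespace (and its coercion methods) is loaded before methods::as.
to_csparse <- function(m) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

stop_classed <- function(class, msg, ...) {
  stop(structure(class = c(class, "sigtransfer_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
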