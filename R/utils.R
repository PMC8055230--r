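#' @importFrom rlang abort warn .data
#' @importFrom stats plogis qlogis rnorm runif rbeta rgamma rbinom rnbinom
#'   median quantile sd setNames dbeta approx
NULL

# Numerically stable log(sum(exp(x))) along rows of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

clip01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# log of the standard logistic density evaluated at x, stable for |x| large
dlogis_log <- function(x) -abs(x) - 2 * log1p(exp(-abs(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
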