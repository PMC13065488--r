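# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats plogis qlogis rbinom rpois runif rnorm rlnorm sd
#'   quantile dbinom dnorm dgamma rgamma dunif var median setNames
#' @importFrom utils read.csv write.csv
NULL

## log() guarded against exact zeros from probabilities at machine limits
log_safe <- function(x) log(pmax(x, .Machine$double.xmin))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_param <- function(...) stop(..., call. = FALSE)

## Run expr with a temporary RNG state seeded by `seed`, restoring the global
## stream afterwards so generator calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop_param("`seed` must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Standardize columns; optionally with externally supplied statistics.
standardize_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale < .Machine$double.eps] <- 1
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
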