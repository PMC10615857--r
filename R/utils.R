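#' @useDynLib mitomorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif setNames t.test wilcox.test var
#' @importFrom utils read.csv write.csv head tail
#' @importFrom grDevices chull
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

NM_PER_UM <- 1000
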