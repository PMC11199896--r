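#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif predict sd var fft
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom Rcpp evalCpp
#' @useDynLib errpnet, .registration = TRUE
NULL

#' Derive a child seed from a parent seed and a label
#'
#' Stable integer hashing used to give every subject, fold or replicate its
#' own reproducible random stream regardless of generation order. The result
#' is always a positive integer below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... further scalar components (strings or integers) identifying the
#'   child stream, e.g. a subject index.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, "subject", 3)
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  m <- 2147483647
  for (p in parts) {
    for (code in utf8ToInt(p)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 31 + 17) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

## evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## squared Euclidean cross-distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
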