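#' @useDynLib mosr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif sd var cor quantile pnorm setNames
#' @importFrom utils head tail write.table read.delim modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic primitives in the
# package route their randomness through this so that one master seed fans
# out reproducibly.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Derive independent child seeds from a master seed
#'
#' One master seed deterministically fans out to the phantom generator,
#' augmentation, slice sampling and weight initialization.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @param labels optional character labels for the returned vector.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
seed_streams <- function(master, n, labels = NULL) {
  s <- with_seed(master, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

stop_mosr <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
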