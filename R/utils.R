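#' @keywords internal
#' @useDynLib nervedecodr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Stable digest of an R object
#'
#' Used to stamp configurations and fitted models so that artifacts can be
#' matched to the exact settings that produced them.
#'
#' @param x any serializable R object
#' @return a character scalar digest
#' @export
config_hash <- function(x) rlang::hash(x)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
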