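#' @useDynLib mrclone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats lm coef dbinom pbinom rbinom rpois rnorm runif
#'   p.adjust t.test qnorm sd dist median setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. `seed = NULL` leaves the current stream in place.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

## Deterministic sub-seed derivation: keeps all derived seeds < 2^31 and
## well separated for distinct (seed, salt) pairs.
subSeed <- function(seed, salt) {
    if (is.null(seed))
        return(NULL)
    (as.integer(seed) * 48271 + as.integer(salt)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isAutosome <- function(chrom) {
    !grepl("(X|Y|M|MT)$", as.character(chrom), ignore.case = TRUE)
}
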