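#' @import methods
#' @importFrom stats chisq.test fisher.test phyper p.adjust kmeans hclust
#'   dist quantile rnorm runif setNames sd pt qt median format.pval dhyper
#' @importFrom utils read.table write.table packageVersion head
NULL

## Run an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards so library code never
## perturbs user-level randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible stage-specific seed from a global seed
#'
#' Each pipeline stage draws its randomness from a seed derived by stable
#' hashing of the stage name, so stages are independently reproducible and
#' inserting a new stage does not shift the streams of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer in \code{[0, 2^31)}.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69991 + h * 7919) %% 2147483647)
}

## small input validators -----------------------------------------------------

assertProportion <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single proportion in [0, 1]", call. = FALSE)
  invisible(x)
}

assertCount <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

assertDna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L ||
      grepl("[^ACGTRYSWKMBDHVN]", x))
    stop(what, " must be a single IUPAC DNA string", call. = FALSE)
  invisible(x)
}
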