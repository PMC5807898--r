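#' @importFrom methods new validObject is slot slotNames show setValidity
#' @importFrom stats prcomp rlnorm rmultinom rpois runif setNames cov var
#' @importFrom utils read.delim write.table head
NULL

# Classed conditions so callers can distinguish failure modes programmatically.
vmStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "viromassError")))
}

vmAssert <- function(ok, class, msg) {
  if (!isTRUE(ok)) vmStop(class, msg)
  invisible(TRUE)
}

#' Display rounding conventions
#'
#' Counts and genome-copy abundances are displayed at two significant figures
#' (scientific-notation style), virus-to-cell ratios at two decimals, and
#' percentages at one decimal. Unrounded values are always retained alongside
#' for computation.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
roundCopies <- function(x) signif(x, 2)

#' @rdname roundCopies
#' @export
roundVcr <- function(x) round(x, 2)

#' @rdname roundCopies
#' @export
roundPercent <- function(x) round(x, 1)

#' @rdname roundCopies
#' @export
roundRatio1sf <- function(x) signif(x, 1)

# Deterministic sub-seed per named random stream: all sub-seeds are drawn from
# the root seed up front, so adding a stream at the end of the table never
# perturbs the draws of existing streams.
.streamTable <- c(community = 1L, masses = 2L, profiles = 3L,
                  counts = 4L, hits = 5L, reads = 6L)

streamSeed <- function(seed, stream) {
  idx <- .streamTable[[stream]]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, length(.streamTable))[idx]
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sub
}

withStream <- function(seed, stream, expr) {
  set.seed(streamSeed(seed, stream))
  expr
}

# Strict header check for tabular interfaces.
checkHeader <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  vmAssert(length(missing) == 0L, "viromassHeaderError",
           sprintf("%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", ")))
  invisible(df)
}
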