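#' @useDynLib lncregnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median prcomp pnorm pt qnorm p.adjust rnorm runif
#'   rlnorm rnbinom sd var quantile setNames t.test complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's random-number state so that fixture
#' generation does not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Gap distance between two genomic intervals
#'
#' Coordinate-difference convention: overlapping or adjacent intervals have
#' distance 0; disjoint intervals are separated by `start2 - end1` (or the
#' mirror image), so an interval whose edge lies exactly d bp from another
#' edge has distance d. All arguments are vectorised 1-based inclusive
#' coordinates.
#'
#' @param start1,end1,start2,end2 numeric vectors of interval coordinates.
#' @return Non-negative numeric vector of distances in bp.
#' @export
gap_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Pooled two-group mean
#'
#' Size-weighted mean of two group means, used as a consistency check that
#' reported per-group means and an overall mean agree.
#'
#' @param mean_a,mean_b group means.
#' @param n_a,n_b group sizes.
#' @return `(n_a * mean_a + n_b * mean_b) / (n_a + n_b)`.
#' @export
pooled_group_mean <- function(mean_a, mean_b, n_a, n_b) {
  (n_a * mean_a + n_b * mean_b) / (n_a + n_b)
}

# correlation with zero-variance columns mapped to 0 instead of NA;
# returns the number of affected pairs via attribute "n_zero_var"
safe_cor <- function(x, y = NULL) {
  r <- suppressWarnings(cor(x, y))
  nz <- sum(is.na(r))
  r[is.na(r)] <- 0
  attr(r, "n_zero_var") <- nz
  r
}
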