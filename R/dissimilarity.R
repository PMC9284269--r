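#' Per-attribute ranges of a feature matrix
#'
#' Columnwise minimum and maximum over all samples. These ranges are the
#' normalising denominators of the range-normalised dissimilarity: each
#' attribute contributes \code{|x_is - x_js| / (max_s - min_s)} to the
#' dissimilarity between samples \code{i} and \code{j}.
#'
#' @param x Numeric matrix, samples in rows, attributes in columns. All
#'   values must be finite.
#' @return A list with numeric vectors \code{min} and \code{max} (length
#'   \code{ncol(x)}) and \code{range = max - min}.
#' @examples
#' attribute_ranges(cbind(a = c(0, 1, 4, 5)))
#' @export
attribute_ranges <- function(x) {
  x <- as_feature_matrix(x)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  list(min = mins, max = maxs, range = maxs - mins)
}

#' Range-normalised dissimilarity matrix
#'
#' Builds the n-by-n symmetric dissimilarity matrix whose entry
#' \code{d_ij} is the sum over attributes of the absolute difference
#' divided by that attribute's range over the whole data set,
#' \deqn{d_{ij} = \sum_{s=1}^{p} |x_{is} - x_{js}| / (\max_s - \min_s).}
#' A constant attribute (zero range) contributes 0 rather than NaN: a
#' feature identical in every cell carries no dissimilarity information.
#' Entries therefore lie in \code{[0, p]}, with a zero diagonal.
#'
#' The returned object also carries the three summary statistics the
#' dynamic-radius model consumes: \code{mean_d}, the average over all
#' \code{n^2} entries (the zero diagonal included, as the defining
#' formula divides by \code{n^2}); \code{max_d}; and
#' \code{min_d_offdiag}, the minimum over off-diagonal entries only
#' (self-pairs are always 0 and are excluded, duplicate points are not).
#'
#' @param x Numeric matrix (samples x attributes), or anything
#'   \code{as.matrix} can coerce to one. Needs at least 2 rows.
#' @param ranges Optional precomputed \code{\link{attribute_ranges}};
#'   must come from the same data.
#' @return An object of class \code{"d3k_dissim"}: the dense dissimilarity
#'   matrix with attributes \code{mean_d}, \code{max_d},
#'   \code{min_d_offdiag}, \code{n} and \code{p}.
#' @examples
#' D <- dissimilarity_matrix(cbind(c(0, 1, 4, 5)))
#' unclass(D)[1, ]              # 0.0 0.2 0.8 1.0
#' attr(D, "mean_d")            # 0.45
#' @seealso [diss_summary()], [dynamic_T()], [select_centers()]
#' @export
dissimilarity_matrix <- function(x, ranges = NULL) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n < 2L)
    stop("dissimilarity matrix needs at least 2 samples")
  if (is.null(ranges)) ranges <- attribute_ranges(x)
  rng <- ranges$range
  if (length(rng) != ncol(x))
    stop("'ranges' does not match the number of attributes")
  # scale each attribute by its range; zero-range attributes drop out
  keep <- rng > 0
  if (any(keep)) {
    xs <- sweep(x[, keep, drop = FALSE], 2L, rng[keep], "/")
    d <- as.matrix(stats::dist(xs, method = "manhattan"))
  } else {
    d <- matrix(0, n, n)
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  new_d3k_dissim(d, p = ncol(x))
}

new_d3k_dissim <- function(d, p) {
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  structure(
    d,
    mean_d = sum(d) / n^2,
    max_d = max(d),
    min_d_offdiag = min(off),
    n = n,
    p = p,
    class = c("d3k_dissim", "matrix", "array")
  )
}

#' Summary statistics of a dissimilarity matrix
#'
#' @param D A \code{"d3k_dissim"} object from
#'   \code{\link{dissimilarity_matrix}}, or a plain symmetric matrix with
#'   zero diagonal (statistics are then computed on the spot).
#' @return A list with \code{mean_d} (average over all \code{n^2}
#'   entries, diagonal included), \code{max_d}, and \code{min_d_offdiag}
#'   (minimum over \code{i != j}).
#' @examples
#' D <- dissimilarity_matrix(cbind(c(0, 1, 4, 5)))
#' diss_summary(D)   # mean 0.45, max 1, min off-diagonal 0.2
#' @export
diss_summary <- function(D) {
  if (inherits(D, "d3k_dissim")) {
    return(list(mean_d = attr(D, "mean_d"),
                max_d = attr(D, "max_d"),
                min_d_offdiag = attr(D, "min_d_offdiag")))
  }
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L || ncol(D) != n)
    stop("'D' must be a square dissimilarity matrix with n >= 2")
  list(mean_d = sum(D) / n^2,
       max_d = max(D),
       min_d_offdiag = min(D[row(D) != col(D)]))
}

#' @export
print.d3k_dissim <- function(x, ...) {
  cat(sprintf("Range-normalised dissimilarity matrix: %d x %d (p = %d attributes)\n",
              attr(x, "n"), attr(x, "n"), attr(x, "p")))
  cat(sprintf("  mean = %.6g   max = %.6g   min (off-diagonal) = %.6g\n",
              attr(x, "mean_d"), attr(x, "max_d"), attr(x, "min_d_offdiag")))
  invisible(x)
}

# coerce to a plain finite numeric matrix; shared validation
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  if (ncol(x) < 1L) stop("feature matrix needs at least one attribute")
  x
}
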