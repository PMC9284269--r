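#' log1p transform of a non-negative expression matrix
#'
#' Elementwise \code{log(1 + x)}, the conventional variance-stabilising
#' transform for count data; shape and dimnames are preserved and zero
#' counts stay zero.
#'
#' @param x Numeric matrix with all values >= 0.
#' @return Matrix of the same shape.
#' @export
log1p_transform <- function(x) {
  x <- as_feature_matrix(x)
  if (any(x < 0)) stop("log1p transform requires non-negative values")
  log1p(x)
}

#' Low-dimensional embedding of a feature matrix
#'
#' Delegates to an established embedding implementation; the clustering
#' method itself is embedding-agnostic, but on single-cell data a 3-D
#' t-SNE embedding is the recommended preprocessing, which is the
#' default here. \code{method = "none"} returns the input unchanged so
#' the algorithm core can run on raw features.
#'
#' The embedding is a pure function of \code{(x, method, dims, seed)}:
#' the same call yields the same matrix.
#'
#' @param x Numeric feature matrix (samples x attributes).
#' @param method \code{"none"}, \code{"tsne"} (via \pkg{Rtsne}) or
#'   \code{"pca"} (via \code{\link[stats]{prcomp}}).
#' @param dims Output dimensionality (default 3); must be < ncol(x).
#' @param seed Integer seed controlling the stochastic t-SNE optimiser.
#' @param perplexity t-SNE perplexity; the default
#'   \code{min(30, (n - 1) / 3)} stays valid on small data sets.
#' @return An n x dims numeric matrix (or \code{x} itself for
#'   \code{"none"}).
#' @export
embed_features <- function(x, method = c("tsne", "none", "pca"), dims = 3L,
                           seed = 1L, perplexity = NULL) {
  method <- match.arg(method)
  if (method == "none") return(x)
  x <- as_feature_matrix(x)
  dims <- as.integer(dims)
  if (dims < 2L) stop("'dims' must be at least 2")
  if (dims >= ncol(x))
    stop(sprintf("cannot embed %d attributes into %d dimensions", ncol(x), dims))
  if (nrow(x) < dims + 1L) stop("need at least dims + 1 samples to embed")

  if (method == "pca") {
    emb <- stats::prcomp(x, rank. = dims)$x[, seq_len(dims), drop = FALSE]
  } else {
    if (is.null(perplexity)) perplexity <- min(30, (nrow(x) - 1) / 3)
    set.seed(as.integer(seed))
    emb <- Rtsne::Rtsne(x, dims = dims, perplexity = perplexity,
                        check_duplicates = FALSE, pca = TRUE,
                        max_iter = 1000, verbose = FALSE)$Y
  }
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0(toupper(method), seq_len(dims))
  emb
}
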