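#' Dissimilarity-density-dynamic-radius K-means clustering
#'
#' Fits the full D3K pipeline to a feature matrix: (optional) log1p
#' transform and low-dimensional embedding, range-normalised L1
#' dissimilarity matrix, dynamic radius \code{r = mean(d) / T} with T
#' from the fitted parameter model (or supplied manually), iterative
#' density/weight-based selection of initial centres — which also
#' determines the cluster count K — and seeded Lloyd refinement.
#'
#' Unlike random-restart K-means, the whole procedure is deterministic
#' given the inputs and \code{seed} (the seed only drives the t-SNE
#' embedding, when used). The hint \code{k_hint} enters only through the
#' dynamic-radius parameter, whose K coefficient is small; the K
#' actually used for refinement is the emergent number of centres, and
#' a message is emitted when the two differ.
#'
#' @param x Numeric matrix (samples/cells in rows) or data frame.
#' @param k_hint Approximate number of clusters, used by the dynamic
#'   radius parameter model (ignored when \code{T} is supplied).
#' @param T Optional manual dynamic radius parameter (> 0); default
#'   \code{NULL} computes it from \code{k_hint} and the dissimilarity
#'   summary statistics.
#' @param mode Seeding mode, \code{"strict"} or \code{"robust"}; see
#'   \code{\link{select_centers}}.
#' @param log1p Apply \code{\link{log1p_transform}} first (for
#'   non-negative count input).
#' @param embed Embedding applied before the dissimilarity computation:
#'   \code{"none"} (default), \code{"tsne"} or \code{"pca"}; see
#'   \code{\link{embed_features}}.
#' @param dims Embedding dimensionality (default 3).
#' @param distance Refinement distance, \code{"euclidean"} or
#'   \code{"d3k"}; see \code{\link{lloyd_refine}}.
#' @param max_iter,tol Lloyd refinement controls.
#' @param seed Integer seed for the embedding step.
#' @param keep_diss Keep the n x n dissimilarity matrix in the fit.
#' @return An object of class \code{"d3k"}: a list with
#'   \code{labels} (named integer vector, 1..K), \code{k},
#'   \code{centroids}, \code{centers_idx} (seed sample indices),
#'   \code{T}, \code{r}, \code{k_hint}, \code{diss_summary},
#'   \code{seeding} (\code{"d3k_seeding"}), \code{n_iter},
#'   \code{converged}, \code{objective}, \code{features} (the matrix
#'   the dissimilarity was built from), \code{config}, and optionally
#'   \code{D}.
#' @examples
#' fit <- d3k(cbind(c(0, 1, 4, 5)), k_hint = 2)
#' fit$labels                       # 1 1 2 2
#' fit$T                            # 0.67625
#' @seealso [select_centers()], [lloyd_refine()], [cluster_metrics()]
#' @export
d3k <- function(x, k_hint = 2L, T = NULL, mode = c("strict", "robust"),
                log1p = FALSE, embed = c("none", "tsne", "pca"),
                dims = 3L, distance = c("euclidean", "d3k"),
                max_iter = 300L, tol = 1e-6, seed = 1L,
                keep_diss = FALSE) {
  mode <- match.arg(mode)
  embed <- match.arg(embed)
  distance <- match.arg(distance)
  cl <- match.call()

  x <- as_feature_matrix(x)
  if (log1p) x <- log1p_transform(x)
  feats <- embed_features(x, method = embed, dims = dims, seed = seed)

  D <- dissimilarity_matrix(feats)
  stats <- diss_summary(D)
  T_source <- if (is.null(T)) "auto" else "manual"
  if (is.null(T)) {
    T <- dynamic_T(k_hint, stats$mean_d, stats$max_d, stats$min_d_offdiag)
  } else if (!is.finite(T) || T <= 0) {
    stop("manual 'T' must be a positive number")
  }
  r <- dynamic_radius(stats$mean_d, T)
  if (r <= 0)
    stop("mean dissimilarity is 0 (all samples identical); cannot cluster")

  seeding <- select_centers(D, r, mode = mode)
  if (seeding$k != k_hint)
    message(sprintf("emergent K = %d differs from k_hint = %d", seeding$k,
                    k_hint))
  refined <- lloyd_refine(feats, seeding$centers, max_iter = max_iter,
                          tol = tol, distance = distance)

  labels <- refined$labels
  names(labels) <- rownames(feats) %||% paste0("cell_", seq_along(labels))

  structure(list(
    labels = labels, k = refined$k, centroids = refined$centroids,
    centers_idx = seeding$centers, T = T, r = r, k_hint = as.integer(k_hint),
    diss_summary = stats, seeding = seeding,
    n_iter = refined$n_iter, converged = refined$converged,
    objective = refined$objective, objective_trace = refined$objective_trace,
    distance = distance, features = feats,
    D = if (keep_diss) D else NULL,
    config = list(k_hint = as.integer(k_hint), T = T, T_source = T_source,
                  mode = mode, log1p = log1p, embed = embed,
                  dims = as.integer(dims), distance = distance,
                  max_iter = as.integer(max_iter), tol = tol,
                  seed = as.integer(seed)),
    call = cl), class = "d3k")
}

#' @export
print.d3k <- function(x, ...) {
  cat("D3K clustering\n")
  cat(sprintf("  n = %d cells, K = %d clusters (k_hint = %d)\n",
              length(x$labels), x$k, x$k_hint))
  cat(sprintf("  T = %.6g (%s), r = %.6g\n", x$T, x$config$T_source, x$r))
  cat(sprintf("  refinement: %d iteration(s), %s, objective %.6g\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$objective))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.d3k <- function(object, ...) {
  structure(list(fit = object), class = "summary.d3k")
}

#' @export
print.summary.d3k <- function(x, ...) {
  f <- x$fit
  print(f)
  s <- f$diss_summary
  cat(sprintf("  dissimilarity: mean %.4g, max %.4g, min off-diagonal %.4g\n",
              s$mean_d, s$max_d, s$min_d_offdiag))
  cat("  seed points (selection order):",
      paste(f$centers_idx, collapse = ", "), "\n")
  if (any(f$seeding$noise))
    cat(sprintf("  noise points flagged at seeding: %d\n",
                sum(f$seeding$noise)))
  invisible(x)
}

#' Cluster labels of a D3K fit
#' @param object A \code{"d3k"} object.
#' @param ... Unused.
#' @return Named integer vector of cluster labels in 1..K.
#' @export
fitted.d3k <- function(object, ...) object$labels

#' Assign new samples to the nearest D3K centroid
#'
#' @param object A \code{"d3k"} object.
#' @param newdata Matrix with the same attributes as the features the
#'   fit clustered (after any embedding; prediction is only meaningful
#'   for \code{embed = "none"} fits, since a t-SNE embedding does not
#'   extend to new points).
#' @param ... Unused.
#' @return Integer vector of cluster assignments.
#' @export
predict.d3k <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != ncol(object$centroids))
    stop("'newdata' must have ", ncol(object$centroids), " attributes")
  if (object$distance == "d3k") {
    rng <- attribute_ranges(object$features)$range
    keep <- rng > 0
    scale_rows <- function(m) sweep(m[, keep, drop = FALSE], 2L, rng[keep], "/")
    d <- point_centroid_dist(scale_rows(newdata),
                             scale_rows(object$centroids), "d3k")
  } else {
    d <- point_centroid_dist(newdata, object$centroids, "euclidean")
  }
  max.col(-d, ties.method = "first")
}

#' Plot a D3K clustering
#'
#' Scatter of the first two feature dimensions, coloured by cluster,
#' with seed points circled and final centroids crossed.
#'
#' @param x A \code{"d3k"} object.
#' @param dims Length-2 integer vector of feature columns to plot.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.d3k <- function(x, dims = c(1L, 2L), ...) {
  f <- x$features
  if (ncol(f) == 1L) f <- cbind(f, seq_len(nrow(f)))
  pal <- grDevices::hcl.colors(max(x$k, 2L), "Dark 3")
  graphics::plot(f[, dims[1L]], f[, dims[2L]], col = pal[x$labels],
                 pch = 16, xlab = colnames(f)[dims[1L]] %||% "dim 1",
                 ylab = colnames(f)[dims[2L]] %||% "dim 2",
                 main = sprintf("D3K clustering (K = %d)", x$k), ...)
  graphics::points(f[x$centers_idx, dims[1L]], f[x$centers_idx, dims[2L]],
                   pch = 1, cex = 2.2, lwd = 2)
  if (all(dims <= ncol(x$centroids)))
    graphics::points(x$centroids[, dims[1L]], x$centroids[, dims[2L]],
                     pch = 4, cex = 1.6, lwd = 2)
  invisible(x)
}
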