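#' Seeded Lloyd refinement
#'
#' Refines a clustering from a fixed set of initial centres by
#' alternating nearest-centroid assignment and centroid updates until
#' the assignment is unchanged, the largest centroid displacement falls
#' below \code{tol}, or \code{max_iter} is reached. There are no random
#' restarts: with fixed inputs the run is fully deterministic, which is
#' the point of a deterministic seeding.
#'
#' Two distance/update pairings are available, both with a monotonically
#' non-increasing objective:
#' \describe{
#'   \item{\code{"euclidean"}}{squared Euclidean distance with
#'     attribute-wise mean updates (plain K-means); the objective is the
#'     within-cluster sum of squared distances.}
#'   \item{\code{"d3k"}}{the range-normalised L1 dissimilarity (the same
#'     metric the seeding uses, with attribute ranges fixed from the full
#'     data set) with attribute-wise \emph{median} updates, which
#'     minimise an L1 objective; the objective is the sum of
#'     dissimilarities to the assigned centroid.}
#' }
#'
#' A cluster that empties during assignment is re-seeded with the point
#' farthest from its current centroid, so every cluster is non-empty on
#' output.
#'
#' @param x Numeric feature matrix (samples x attributes).
#' @param init_centers Integer vector of distinct row indices of \code{x}
#'   used as initial centroids (in order).
#' @param max_iter Maximum number of assignment/update iterations.
#' @param tol Convergence tolerance on the maximum centroid displacement
#'   (Euclidean norm per centroid).
#' @param distance \code{"euclidean"} or \code{"d3k"}.
#' @return An object of class \code{"d3k_refine"}: a list with integer
#'   \code{labels} in \code{1..K}, the \code{centroids} matrix (K x p),
#'   \code{n_iter}, logical \code{converged}, final \code{objective} and
#'   the per-iteration \code{objective_trace}.
#' @examples
#' x <- cbind(c(0, 1, 4, 5))
#' lloyd_refine(x, init_centers = c(2, 4))$labels   # 1 1 2 2
#' @export
lloyd_refine <- function(x, init_centers, max_iter = 300L, tol = 1e-6,
                         distance = c("euclidean", "d3k")) {
  distance <- match.arg(distance)
  x <- as_feature_matrix(x)
  n <- nrow(x); p <- ncol(x)
  init_centers <- as.integer(init_centers)
  k <- length(init_centers)
  if (k < 1L) stop("need at least one initial centre")
  if (k > n) stop("more centres than samples")
  if (anyDuplicated(init_centers))
    stop("initial centres must be distinct indices")
  if (any(init_centers < 1L | init_centers > n))
    stop("initial centre index out of range")
  stopifnot(max_iter >= 1L)

  # work in range-scaled coordinates for the d3k metric so distances are
  # the seeding dissimilarities; ranges are a global property of x
  if (distance == "d3k") {
    rng <- attribute_ranges(x)$range
    keep <- rng > 0
    xw <- if (any(keep)) sweep(x[, keep, drop = FALSE], 2L, rng[keep], "/")
          else matrix(0, n, 1L)
  } else {
    xw <- x
  }

  centroids <- xw[init_centers, , drop = FALSE]
  labels <- integer(n)
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    dmat <- point_centroid_dist(xw, centroids, distance)
    new_labels <- max.col(-dmat, ties.method = "first")

    # re-seed empty clusters with the farthest point from its centroid
    for (c_empty in setdiff(seq_len(k), unique(new_labels))) {
      far <- which.max(dmat[cbind(seq_len(n), new_labels)])
      new_labels[far] <- c_empty
      centroids[c_empty, ] <- xw[far, ]
      dmat[, c_empty] <- point_centroid_dist(xw, centroids[c_empty, ,
                                                           drop = FALSE],
                                             distance)[, 1L]
    }

    obj_trace <- c(obj_trace, sum(dmat[cbind(seq_len(n), new_labels)]))
    labels_unchanged <- iter > 1L && all(new_labels == labels)
    labels <- new_labels

    new_centroids <- update_centroids(xw, labels, k, centroids, distance)
    shift <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    if (labels_unchanged || shift < tol) { converged <- TRUE; break }
  }

  # report centroids on the original feature scale
  out_centroids <- update_centroids(x, labels, k,
                                    x[init_centers, , drop = FALSE],
                                    distance)
  colnames(out_centroids) <- colnames(x)

  structure(list(labels = labels, centroids = out_centroids, k = k,
                 n_iter = iter, converged = converged,
                 objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace, distance = distance),
            class = "d3k_refine")
}

# n x k matrix of point-to-centroid distances (squared Euclidean or L1
# in pre-scaled coordinates)
point_centroid_dist <- function(xw, centroids, distance) {
  n <- nrow(xw); k <- nrow(centroids)
  if (distance == "euclidean") {
    cross <- tcrossprod(xw, centroids)
    d <- outer(rowSums(xw^2), rowSums(centroids^2), "+") - 2 * cross
    pmax(d, 0)
  } else {
    d <- matrix(0, n, k)
    for (j in seq_len(k))
      d[, j] <- rowSums(abs(sweep(xw, 2L, centroids[j, ], "-")))
    d
  }
}

# mean updates for the Euclidean pairing, median updates for L1
update_centroids <- function(xw, labels, k, fallback, distance) {
  out <- fallback
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (!length(members)) next
    xm <- xw[members, , drop = FALSE]
    out[j, ] <- if (distance == "euclidean") colMeans(xm)
                else apply(xm, 2L, stats::median)
  }
  out
}

#' @export
print.d3k_refine <- function(x, ...) {
  cat(sprintf(
    "Seeded Lloyd refinement (%s): K = %d, %d iteration(s), %s, objective %.6g\n",
    x$distance, x$k, x$n_iter,
    if (x$converged) "converged" else "not converged", x$objective))
  invisible(x)
}
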