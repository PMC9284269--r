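#' Gaussian blobs with optional uniform background noise
#'
#' Generates the low-dimensional structure the seeding procedure
#' assumes: K isotropic Gaussian clusters whose centroids are at least
#' \code{separation * within_sd} apart (Euclidean), plus an optional
#' fraction of uniform background points. Noise points are drawn over
#' the bounding box of the clustered points inflated by 20%, so they
#' are genuinely low-density relative to the blobs, and carry the
#' reserved label \code{"noise"}.
#'
#' @param k Number of clusters.
#' @param points_per_cluster Integer, recycled to length \code{k}.
#' @param dims Dimensionality.
#' @param separation Minimum pairwise centroid distance, in units of
#'   \code{within_sd}.
#' @param within_sd Isotropic within-cluster standard deviation.
#' @param noise_fraction Number of uniform noise points, as a fraction
#'   of the clustered points (in \code{[0, 1)}).
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A list with \code{x} (matrix, clustered points first, then
#'   noise), \code{labels} (character: \code{"1"..k} and
#'   \code{"noise"}), and \code{centroids} (the generating k x dims
#'   matrix).
#' @examples
#' b <- make_blobs(k = 3, points_per_cluster = 50, seed = 1)
#' table(b$labels)
#' @export
make_blobs <- function(k = 3L, points_per_cluster = 50L, dims = 3L,
                       separation = 8, within_sd = 1, noise_fraction = 0,
                       seed = 1L) {
  stopifnot(k >= 1L, dims >= 1L, separation > 0, within_sd > 0,
            noise_fraction >= 0, noise_fraction < 1)
  sizes <- rep_len(as.integer(points_per_cluster), k)
  stopifnot(all(sizes >= 1L))
  set.seed(as.integer(seed))

  # rejection-sample centroids in a box wide enough to hold k separated
  # blobs; retry bounded so an infeasible spec errors out
  min_gap <- separation * within_sd
  box <- min_gap * max(2, ceiling(k^(1 / dims)) + 1)
  centroids <- NULL
  for (attempt in seq_len(500L)) {
    cand <- matrix(stats::runif(k * dims, 0, box), k, dims)
    if (k == 1L || min(stats::dist(cand)) >= min_gap) { centroids <- cand; break }
  }
  if (is.null(centroids))
    stop("could not place ", k, " centroids at the requested separation")

  n_signal <- sum(sizes)
  x <- matrix(stats::rnorm(n_signal * dims, sd = within_sd), n_signal, dims) +
    centroids[rep(seq_len(k), sizes), , drop = FALSE]
  labels <- as.character(rep(seq_len(k), sizes))

  n_noise <- round(noise_fraction * n_signal)
  if (n_noise > 0) {
    lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
    pad <- 0.2 * (hi - lo)
    noise <- sapply(seq_len(dims), function(j)
      stats::runif(n_noise, lo[j] - pad[j], hi[j] + pad[j]))
    noise <- matrix(noise, n_noise, dims)
    x <- rbind(x, noise)
    labels <- c(labels, rep("noise", n_noise))
  }
  rownames(x) <- paste0("cell_", seq_len(nrow(x)))
  colnames(x) <- paste0("dim", seq_len(dims))
  list(x = x, labels = labels, centroids = centroids)
}

#' Negative-binomial count matrix with marker-gene blocks
#'
#' Simulates a cells x genes count matrix with the Table-1-style
#' structure single-cell clustering is evaluated on: background genes
#' share a common negative-binomial mean, each cluster owns a block of
#' marker genes whose mean is multiplied by \code{fold_change} in that
#' cluster, and independent dropout zeroes each entry with fixed
#' probability. Counts are NB with variance
#' \code{mu + mu^2 / dispersion}.
#'
#' @param k Number of clusters.
#' @param cells_per_cluster Integer, recycled to length \code{k}.
#' @param n_genes Total number of genes.
#' @param n_marker_genes Markers per cluster; \code{k * n_marker_genes}
#'   must not exceed \code{n_genes}.
#' @param base_mean Background NB mean.
#' @param fold_change Marker mean multiplier (>= 1) in the owning
#'   cluster; 1 gives a signal-free null matrix.
#' @param dispersion NB size parameter (> 0); larger is closer to
#'   Poisson.
#' @param dropout_rate Probability an entry is zeroed, in \code{[0, 1)}.
#' @param seed Integer seed.
#' @return A list with \code{counts} (cells x genes integer matrix) and
#'   \code{labels} (character \code{"1"..k}).
#' @examples
#' sim <- make_counts(k = 2, cells_per_cluster = 10, n_genes = 50, seed = 1)
#' dim(sim$counts)
#' @export
make_counts <- function(k = 3L, cells_per_cluster = 60L, n_genes = 200L,
                        n_marker_genes = 10L, base_mean = 2,
                        fold_change = 8, dispersion = 2,
                        dropout_rate = 0.3, seed = 1L) {
  stopifnot(k >= 1L, n_genes >= 1L, n_marker_genes >= 0L,
            base_mean > 0, fold_change >= 1, dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (k * n_marker_genes > n_genes)
    stop("marker blocks exceed the total number of genes")
  sizes <- rep_len(as.integer(cells_per_cluster), k)
  set.seed(as.integer(seed))

  n <- sum(sizes)
  labels <- rep(seq_len(k), sizes)
  mu <- matrix(base_mean, n, n_genes)
  for (cl in seq_len(k)) {
    marker_cols <- ((cl - 1L) * n_marker_genes + 1L):(cl * n_marker_genes)
    if (n_marker_genes > 0L)
      mu[labels == cl, marker_cols] <- base_mean * fold_change
  }
  counts <- matrix(stats::rnbinom(n * n_genes, mu = mu, size = dispersion),
                   n, n_genes)
  if (dropout_rate > 0)
    counts <- counts *
      matrix(stats::rbinom(n * n_genes, 1L, 1 - dropout_rate), n, n_genes)
  dimnames(counts) <- list(paste0("cell_", seq_len(n)),
                           paste0("gene_", seq_len(n_genes)))
  list(counts = counts, labels = as.character(labels))
}
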