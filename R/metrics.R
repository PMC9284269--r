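#' Contingency table of two labelings
#'
#' Counts, for every (truth class u, predicted cluster v) pair, the
#' number of points carrying both labels. Row sums give the truth class
#' sizes, column sums the predicted cluster sizes.
#'
#' @param truth,pred Vectors of equal length; any atomic label type.
#' @return An integer matrix with truth classes in rows and predicted
#'   clusters in columns.
#' @export
cluster_contingency <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(truth), length(pred)))
  if (!length(truth)) stop("empty label vectors")
  tab <- table(truth = as.character(truth), pred = as.character(pred))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' External clustering evaluation metrics
#'
#' The four indices used to score a predicted partition against ground
#' truth, all invariant to relabeling of either side and all in
#' \code{[0, 1]}:
#' \describe{
#'   \item{\code{nmi}}{normalised mutual information,
#'     \code{I(U;V) / ((H(U)+H(V))/2)} with natural-log entropies;
#'     defined as 1 when both partitions are trivial (zero entropy).}
#'   \item{\code{f_measure}}{pairwise F-measure: harmonic mean of
#'     precision and recall over the \code{n(n-1)/2} point pairs, where
#'     a "positive" is a pair placed in one cluster.}
#'   \item{\code{accuracy}}{mapped accuracy: fraction of points
#'     correctly classified under the best one-to-one assignment of
#'     predicted clusters to truth classes (Hungarian algorithm on the
#'     contingency table, padded square).}
#'   \item{\code{rand_index}}{classical (unadjusted) Rand index:
#'     fraction of point pairs on which the two partitions agree.}
#' }
#'
#' @param truth,pred Label vectors of equal length, n >= 2.
#' @return An object of class \code{"d3k_metrics"}: a list with
#'   \code{nmi}, \code{f_measure}, \code{accuracy}, \code{rand_index}.
#' @examples
#' cluster_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1))$rand_index  # 1/3
#' @export
cluster_metrics <- function(truth, pred) {
  tab <- cluster_contingency(truth, pred)
  n <- sum(tab)
  if (n < 2L) stop("pair-based metrics need at least 2 points")

  structure(list(nmi = nmi_from_table(tab),
                 f_measure = pairwise_f_from_table(tab),
                 accuracy = mapped_accuracy_from_table(tab),
                 rand_index = rand_from_table(tab)),
            class = "d3k_metrics")
}

#' @export
print.d3k_metrics <- function(x, digits = 4, ...) {
  cat("Clustering evaluation:\n")
  cat(sprintf("  NMI        %.*f\n", digits, x$nmi))
  cat(sprintf("  F-measure  %.*f\n", digits, x$f_measure))
  cat(sprintf("  Accuracy   %.*f\n", digits, x$accuracy))
  cat(sprintf("  Rand index %.*f\n", digits, x$rand_index))
  invisible(x)
}

nmi_from_table <- function(tab) {
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu == 0 && hv == 0) return(1)
  puv <- tab / n
  expct <- outer(pu, pv)
  pos <- puv > 0
  mi <- sum(puv[pos] * log(puv[pos] / expct[pos]))
  mi / ((hu + hv) / 2)
}

# pair counts from a contingency table: choose(n_uv, 2) etc.
pair_counts <- function(tab) {
  n <- sum(tab)
  list(total = choose(n, 2),
       both = sum(choose(tab, 2)),               # same class & same cluster
       truth = sum(choose(rowSums(tab), 2)),     # same class
       pred = sum(choose(colSums(tab), 2)))      # same cluster
}

rand_from_table <- function(tab) {
  pc <- pair_counts(tab)
  agree <- pc$total + 2 * pc$both - pc$truth - pc$pred
  agree / pc$total
}

pairwise_f_from_table <- function(tab) {
  pc <- pair_counts(tab)
  if (pc$pred == 0 && pc$truth == 0) return(1)  # both all-singleton
  precision <- if (pc$pred > 0) pc$both / pc$pred else 0
  recall <- if (pc$truth > 0) pc$both / pc$truth else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

mapped_accuracy_from_table <- function(tab) {
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  assignment <- clue::solve_LSAP(sq, maximum = TRUE)
  sum(sq[cbind(seq_len(k), assignment)]) / sum(tab)
}
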