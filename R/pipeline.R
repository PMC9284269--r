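#' Run the full D3K pipeline on files
#'
#' File-level orchestration: read an expression matrix, fit
#' \code{\link{d3k}}, write labels/centers/report via
#' \code{\link{write_d3k}}, and (when ground-truth labels are supplied)
#' append the evaluation metrics to the report. This is the programmatic
#' equivalent of the command-line \code{cluster} subcommand.
#'
#' @param input Path to the expression matrix (CSV/TSV/MTX).
#' @param out_dir Output directory.
#' @param k_hint Approximate cluster count for the dynamic radius model.
#' @param format,orientation,row_names_file,col_names_file Passed to
#'   \code{\link{read_matrix}}.
#' @param truth Optional path to a ground-truth label file; adds a
#'   \code{metrics.json} output.
#' @param truth_header Logical, passed to \code{\link{read_labels}}.
#' @param ... Further arguments to \code{\link{d3k}} (\code{T},
#'   \code{mode}, \code{log1p}, \code{embed}, \code{dims},
#'   \code{distance}, \code{seed}, ...).
#' @param verbose Print progress.
#' @return The \code{"d3k"} fit, invisibly.
#' @export
run_cluster <- function(input, out_dir, k_hint = 2L,
                        format = "auto", orientation = "cells_in_rows",
                        row_names_file = NULL, col_names_file = NULL,
                        truth = NULL, truth_header = FALSE, ...,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  x <- read_matrix(input, format = format, orientation = orientation,
                   row_names_file = row_names_file,
                   col_names_file = col_names_file)
  say("read %d cells x %d features from %s", nrow(x), ncol(x), input)

  fit <- d3k(x, k_hint = k_hint, ...)
  say("T = %.6g, r = %.6g, emergent K = %d; refinement %s in %d iteration(s)",
      fit$T, fit$r, fit$k, if (fit$converged) "converged" else "stopped",
      fit$n_iter)

  paths <- write_d3k(fit, out_dir)
  say("wrote %s", paste(paths, collapse = ", "))

  if (!is.null(truth)) {
    tl <- read_labels(truth, header = truth_header)
    if (length(tl) != length(fit$labels))
      stop(sprintf("truth has %d labels but the matrix has %d cells",
                   length(tl), length(fit$labels)))
    m <- cluster_metrics(tl, fit$labels)
    jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    say("NMI %.4f  F %.4f  accuracy %.4f  Rand %.4f",
        m$nmi, m$f_measure, m$accuracy, m$rand_index)
  }
  invisible(fit)
}

#' Evaluate a predicted labeling against ground truth, from files
#'
#' Reads two label files and computes the four evaluation indices; the
#' programmatic equivalent of the command-line \code{eval} subcommand.
#'
#' @param truth,pred Paths to label files (one label per line).
#' @param truth_header,pred_header Skip a header line.
#' @return A \code{"d3k_metrics"} object.
#' @export
run_eval <- function(truth, pred, truth_header = FALSE, pred_header = FALSE) {
  tl <- read_labels(truth, header = truth_header)
  pl <- read_labels(pred, header = pred_header)
  cluster_metrics(tl, pl)
}
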