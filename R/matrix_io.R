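#' Read an expression matrix from delimited text or Matrix Market files
#'
#' Reads a cells x genes (or genes x cells) matrix and returns it in the
#' canonical cells-in-rows orientation, transposing when
#' \code{orientation = "cells_in_columns"}. Orientation is never
#' guessed: callers must state it for genes-in-rows files.
#'
#' For delimited text, a header line and a leading row-name column are
#' auto-detected (any non-numeric field in the first line / first
#' column); ragged rows and non-numeric cells raise errors that name
#' the offending line or coordinates. For Matrix Market (\code{.mtx})
#' triplets, duplicate entries are summed per the format's convention,
#' and optional sidecar files (one name per line, e.g. 10x-style
#' \code{barcodes}/\code{features}) supply dimension names. Missing
#' names are replaced by positional identifiers.
#'
#' @param path Path to the matrix file.
#' @param format \code{"auto"} (by extension), \code{"csv"},
#'   \code{"tsv"}, or \code{"mtx"}.
#' @param orientation \code{"cells_in_rows"} (default) or
#'   \code{"cells_in_columns"}.
#' @param row_names_file,col_names_file Optional sidecar name files for
#'   mtx input (names for the rows/columns of the file as stored, i.e.
#'   before any orientation transpose).
#' @return A numeric matrix, cells in rows, with row and column names.
#' @export
read_matrix <- function(path,
                        format = c("auto", "csv", "tsv", "mtx"),
                        orientation = c("cells_in_rows", "cells_in_columns"),
                        row_names_file = NULL, col_names_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", tsv = "tsv", txt = "tsv", "csv")
  }

  m <- if (format == "mtx") {
    read_mtx_dense(path, row_names_file, col_names_file)
  } else {
    read_delim_matrix(path, sep = if (format == "csv") "," else "\t")
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("matrix in ", path, " is empty")
  if (orientation == "cells_in_columns") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  m
}

read_delim_matrix <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) stop("matrix file is empty: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  # an R-style "short" header (one non-numeric field fewer than the data
  # rows, which carry a row-name column) is tolerated before the
  # ragged-row check
  numeric_line1 <- !anyNA(suppressWarnings(as.numeric(trimws(fields[[1L]]))))
  short_header <- length(widths) > 1L && widths[1L] == widths[2L] - 1L &&
    all(widths[-1L] == widths[2L]) && !numeric_line1
  ref_w <- if (short_header) widths[2L] else widths[1L]
  bad <- which(widths != ref_w)
  if (short_header) bad <- bad[bad != 1L]
  if (length(bad)) {
    bad <- bad[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, widths[bad], ref_w))
  }
  fields <- lapply(fields, trimws)

  # locale-independent numeric parse; header/row-name auto-detection
  is_num <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  # header if any field past the first in line 1 is non-numeric (a lone
  # non-numeric first field is a row-name column instead)
  header <- if (length(fields[[1L]]) == 1L) !is_num(fields[[1L]][1L])
            else !all(is_num(fields[[1L]][-1L]))
  col_names <- NULL
  if (header) {
    col_names <- fields[[1L]]
    fields <- fields[-1L]
    if (!length(fields)) stop("matrix file has a header but no data: ", path)
  }
  first_col <- vapply(fields, `[`, character(1), 1L)
  has_rownames <- !all(is_num(first_col))
  row_names <- NULL
  if (has_rownames) {
    row_names <- first_col
    fields <- lapply(fields, `[`, -1L)
    if (!is.null(col_names) && length(col_names) == length(fields[[1L]]) + 1L)
      col_names <- col_names[-1L]
  }

  nr <- length(fields); nc <- length(fields[[1L]])
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    r <- ceiling(bad / nc); c <- bad - (r - 1L) * nc
    stop(sprintf("non-numeric value %s in %s at data row %d, column %d",
                 dQuote(fields[[r]][c]), path, r, c))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  rownames(m) <- row_names
  colnames(m) <- col_names
  m
}

read_mtx_dense <- function(path, row_names_file, col_names_file) {
  sp <- Matrix::readMM(path)
  # dgCMatrix coercion sums duplicate coordinate entries (MM convention)
  m <- as.matrix(methods::as(sp, "CsparseMatrix"))
  read_names <- function(f, expected, what) {
    if (is.null(f)) return(NULL)
    nm <- read_labels(f)
    if (length(nm) != expected)
      stop(sprintf("%s sidecar %s has %d names, matrix has %d %s",
                   what, f, length(nm), expected, what))
    nm
  }
  rownames(m) <- read_names(row_names_file, nrow(m), "row")
  colnames(m) <- read_names(col_names_file, ncol(m), "column")
  m
}

#' Read a label vector
#'
#' One label per line (or a single-column CSV); surrounding whitespace
#' is stripped. A blank interior line is an error; a single trailing
#' newline is tolerated.
#'
#' @param path Path to the label file.
#' @param header Logical; skip the first line (e.g. a \code{"cluster"}
#'   column header).
#' @return Character vector of labels in file order.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (header) lines <- lines[-1L]
  if (!length(lines)) stop("label file is empty: ", path)
  labels <- trimws(lines)
  if (any(labels == "")) {
    stop(sprintf("blank label at line %d of %s",
                 which(labels == "")[1L] + as.integer(header), path))
  }
  labels
}

#' Write labels plain-text
#'
#' Companion to \code{\link{read_labels}}: one label per line, no
#' header, so write-then-read round-trips exactly.
#'
#' @param labels Vector of labels.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Write a fitted D3K clustering to a directory
#'
#' Writes three files: \code{labels.csv} (\code{cell_id,label}),
#' \code{centers.csv} (one row per final centroid), and
#' \code{report.json} with the run's key quantities (K, r, T, the
#' dissimilarity summary statistics, iteration count, convergence flag,
#' the seeding order with each centre's selection weight, noise count,
#' and the configuration echo carried by the fit). Serialisation is
#' deterministic: identical fits produce byte-identical files.
#'
#' @param fit A \code{"d3k"} object from \code{\link{d3k}}.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_d3k <- function(fit, dir) {
  if (!inherits(fit, "d3k")) stop("'fit' must be a d3k object")
  if (!length(fit$labels)) stop("refusing to write an empty clustering result")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)

  labels_path <- file.path(dir, "labels.csv")
  df <- data.frame(cell_id = names(fit$labels) %||%
                     paste0("cell_", seq_along(fit$labels)),
                   label = as.integer(fit$labels))
  utils::write.csv(df, labels_path, row.names = FALSE, quote = FALSE)

  centers_path <- file.path(dir, "centers.csv")
  utils::write.csv(as.data.frame(fit$centroids), centers_path,
                   row.names = FALSE, quote = FALSE)

  report_path <- file.path(dir, "report.json")
  report <- list(
    package = "d3k",
    version = as.character(utils::packageVersion("d3k")),
    k = fit$k,
    k_hint = fit$k_hint,
    T = fit$T,
    r = fit$r,
    dissimilarity = fit$diss_summary,
    seeding = list(centers = fit$seeding$centers,
                   omega_at_selection = fit$seeding$omega_at_selection,
                   n_noise = sum(fit$seeding$noise),
                   mode = fit$seeding$mode),
    refinement = list(n_iter = fit$n_iter, converged = fit$converged,
                      objective = fit$objective,
                      distance = fit$distance),
    config = fit$config
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(labels = labels_path, centers = centers_path,
              report = report_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
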