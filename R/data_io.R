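#' Read an expression matrix
#'
#' Reads a cells x genes expression matrix from dense delimited text (comma
#' or tab, header row, first column = ids) or Matrix Market sparse format
#' with sidecar gene/cell id files.
#'
#' @param path file path (`.csv`/`.tsv`/`.txt` dense, or `.mtx` sparse).
#' @param format `"auto"` (by extension), `"dense"`, or `"mtx"`.
#' @param orientation for dense files: `"cells-rows"` (default) or
#'   `"genes-rows"` (transposed on read).
#' @param genes_file,cells_file sidecar id files for `.mtx` input (one id
#'   per line); for mtx the stored matrix is genes x cells as is
#'   conventional, transposed on read.
#' @param is_count whether values are raw counts; `NULL` = auto-detect
#'   (nonnegative and integral).
#' @return A `"cell_expression"` object: numeric cells x genes matrix with
#'   cell ids as rownames, gene ids as colnames and an `is_count` attribute.
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"),
                            orientation = c("cells-rows", "genes-rows"),
                            genes_file = NULL, cells_file = NULL,
                            is_count = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "dense") {
    tab <- readr::read_delim(path, delim = guess_delim(path),
                             col_types = readr::cols(), progress = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(tab[, -1], is.numeric, logical(1)))[1]
      stop("non-numeric expression values in column '",
           names(tab)[-1][bad], "' of ", path)
    }
    rownames(m) <- ids
    if (orientation == "genes-rows") m <- t(m)
  } else {
    sm <- Matrix::readMM(path)
    m <- t(as.matrix(sm)) # stored genes x cells; we hold cells x genes
    if (is.logical(m)) storage.mode(m) <- "double" # pattern-only file
    if (!is.null(genes_file)) {
      gid <- readr::read_lines(genes_file)
      if (length(gid) != ncol(m)) {
        stop("gene id file length does not match matrix dimension")
      }
      colnames(m) <- gid
    }
    if (!is.null(cells_file)) {
      cid <- readr::read_lines(cells_file)
      if (length(cid) != nrow(m)) {
        stop("cell id file length does not match matrix dimension")
      }
      rownames(m) <- cid
    }
  }
  new_cell_expression(m, is_count = is_count)
}

guess_delim <- function(path) {
  line1 <- readr::read_lines(path, n_max = 1)
  if (grepl("\t", line1)) "\t" else ","
}

new_cell_expression <- function(m, is_count = NULL) {
  if (any(!is.finite(m))) stop("expression matrix contains missing or non-finite entries")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("gene", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicated cell ids")
  if (anyDuplicated(colnames(m))) stop("duplicated gene ids")
  if (is.null(is_count)) {
    is_count <- all(m >= 0) && all(abs(m - round(m)) < 1e-8)
  }
  if (is_count && (any(m < 0) || any(abs(m - round(m)) > 1e-8))) {
    stop("is_count = TRUE but entries are not nonnegative integers")
  }
  structure(m, is_count = is_count, class = c("cell_expression", "matrix", "array"))
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: dense delimited text with an id column,
#' or Matrix Market plus sidecar id files.
#'
#' @param expr a `"cell_expression"` (or plain cells x genes matrix).
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "dense", "mtx"),
                             genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  m <- unclass(expr)
  attr(m, "is_count") <- NULL
  if (format == "dense") {
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    readr::write_csv(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), path)
    if (!is.null(genes_file)) readr::write_lines(colnames(m), genes_file)
    if (!is.null(cells_file)) readr::write_lines(rownames(m), cells_file)
  }
  invisible(path)
}

#' Read cell coordinates
#'
#' Delimited text with two numeric columns (plus optional leading id
#' column). Rows can be re-aligned to a reference cell-id order.
#'
#' @param path file path.
#' @param cell_ids optional id vector (e.g. `rownames` of the expression
#'   matrix); rows are reordered to match, and an error is raised if the
#'   sets of ids differ.
#' @return A tibble with columns `cell_id`, `x`, `y`.
#' @export
read_coordinates <- function(path, cell_ids = NULL) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(), progress = FALSE)
  if (ncol(tab) == 2) {
    out <- tibble::tibble(cell_id = paste0("cell", seq_len(nrow(tab))),
                          x = tab[[1]], y = tab[[2]])
  } else {
    out <- tibble::tibble(cell_id = as.character(tab[[1]]),
                          x = tab[[2]], y = tab[[3]])
  }
  if (!is.numeric(out$x) || !is.numeric(out$y)) {
    stop("non-numeric coordinate column in ", path)
  }
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("non-finite coordinates in ", path)
  }
  if (!is.null(cell_ids)) {
    idx <- match(as.character(cell_ids), out$cell_id)
    if (any(is.na(idx))) {
      stop("coordinate file is missing cells: ",
           paste(head(cell_ids[is.na(idx)], 5), collapse = ", "))
    }
    out <- out[idx, ]
  }
  out
}

#' Read / write a label vector
#'
#' Delimited text with columns `cell_id`, `label`.
#'
#' @param path file path.
#' @param cell_ids optional reference order, as in [read_coordinates()].
#' @return `read_labels()`: a tibble with `cell_id` and integer `label`.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(), progress = FALSE)
  out <- tibble::tibble(cell_id = as.character(tab[[1]]),
                        label = as.integer(tab[[2]]))
  if (!is.null(cell_ids)) {
    idx <- match(as.character(cell_ids), out$cell_id)
    if (any(is.na(idx))) stop("label file is missing cells")
    out <- out[idx, ]
  }
  out
}

#' @rdname read_labels
#' @param labels integer labels aligned with `cell_ids`.
#' @export
write_labels <- function(labels, cell_ids, path) {
  readr::write_csv(tibble::tibble(cell_id = cell_ids,
                                  label = as.integer(labels)), path)
  invisible(path)
}

#' Normalise, log-transform and project expression onto top PCs
#'
#' Standard single-cell preprocessing producing the sampler's observations:
#' per-cell library-size normalisation to the median total count, `log1p`,
#' gene centring (optionally unit-variance scaling) and PCA. Returns the
#' top `n_pcs` PC score vectors as an H x n matrix (PCs in rows, the
#' orientation the sampler consumes). Each component's sign is fixed so its
#' largest-magnitude gene loading is positive, making output reproducible
#' across linear-algebra backends.
#'
#' @param expr a `"cell_expression"` (cells x genes) from
#'   [read_expression()] or [new_cell_expression()].
#' @param n_pcs number of components to keep (default 50).
#' @param normalize scale each cell to the median total count. Intended for
#'   raw counts; a warning is issued for non-count input.
#' @param log_transform apply `log1p` after normalisation.
#' @param scale_genes scale genes to unit variance before PCA (default
#'   FALSE; constant genes are dropped when scaling).
#' @param gene_subset optional character/integer vector restricting to a
#'   gene subset before any processing.
#' @return A `"pc_matrix"`: H x n numeric matrix with cells as columns,
#'   with attributes `sdev` (all component standard deviations) and
#'   `var_explained` (length-H fractions, non-increasing).
#' @export
preprocess_pcs <- function(expr, n_pcs = 50, normalize = TRUE,
                           log_transform = TRUE, scale_genes = FALSE,
                           gene_subset = NULL) {
  m <- unclass(expr)
  attr(m, "is_count") <- NULL
  is_count <- isTRUE(attr(expr, "is_count"))
  if (!is.null(gene_subset)) m <- m[, gene_subset, drop = FALSE]
  if ((normalize || log_transform) && !is_count) {
    warning("normalize/log_transform requested for non-count input; ",
            "set normalize = FALSE, log_transform = FALSE for ",
            "pre-normalised data")
  }
  if (normalize) {
    totals <- rowSums(m)
    if (any(totals == 0)) {
      stop("cells with zero total count: ",
           paste(head(rownames(m)[totals == 0], 5), collapse = ", "))
    }
    m <- m / totals * median(totals)
  }
  if (log_transform) m <- log1p(m)
  if (scale_genes) {
    v <- apply(m, 2, sd)
    m <- m[, v > 0, drop = FALSE]
  }
  max_pcs <- min(nrow(m) - 1, ncol(m))
  if (n_pcs > max_pcs) {
    stop("n_pcs = ", n_pcs, " exceeds the achievable maximum ", max_pcs,
         " = min(n_cells - 1, n_genes)")
  }
  pc <- prcomp(m, center = TRUE, scale. = scale_genes, rank. = n_pcs)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(n_pcs), function(h) {
    w <- pc$rotation[, h]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, `*`)
  y <- t(scores)
  rownames(y) <- paste0("PC", seq_len(n_pcs))
  structure(y,
            sdev = pc$sdev,
            var_explained = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2),
            class = c("pc_matrix", "matrix", "array"))
}
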