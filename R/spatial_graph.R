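#' Directed k-nearest-neighbour graph of cell positions
#'
#' Builds the neighbourhood relation that defines the Potts interaction:
#' cell j is a neighbour of cell i if j is among the k cells closest to i in
#' Euclidean distance. The relation is directed and in general asymmetric
#' (j can be one of i's k nearest neighbours without the converse holding).
#' Distance ties are broken deterministically in favour of the lower cell
#' index. Reverse (in-) edges are precomputed because the full conditional
#' of a cell's label under the directed Potts joint involves both the cells
#' it points to and the cells pointing to it.
#'
#' @param coords cell coordinates: a data frame with columns `x`, `y` (and
#'   optionally `cell_id`), or a numeric matrix with two columns.
#' @param k number of neighbours per cell (default 6).
#' @return An object of class `"knn_graph"`: list with `nb` (n x k integer
#'   matrix of out-neighbour indices), `k`, `n`, `in_ptr`/`in_idx` (reverse
#'   edges in compressed form) and `cell_ids`.
#' @examples
#' g <- knn_graph(data.frame(x = c(0, 1, 3), y = 0), k = 1)
#' g$nb  # 2, 1, 2
#' @export
knn_graph <- function(coords, k = 6) {
  xy <- coords_matrix(coords)
  n <- nrow(xy)
  stopifnot(k >= 1)
  if (n <= k) stop("need more cells (", n, ") than neighbours k = ", k)
  if (any(!is.finite(xy))) stop("coordinates must be finite")
  nb <- knn_build_cpp(xy, as.integer(k))
  new_knn_graph(nb, cell_ids = rownames(xy))
}

new_knn_graph <- function(nb, cell_ids = NULL) {
  n <- nrow(nb)
  # reverse-edge CSR: in-neighbours of i are in_idx[(in_ptr[i]+1):in_ptr[i+1]]
  src <- rep(seq_len(n), times = ncol(nb))
  tgt <- as.vector(nb)
  ord <- order(tgt, src)
  in_idx <- src[ord]
  in_ptr <- c(0L, cumsum(tabulate(tgt, nbins = n)))
  structure(list(nb = nb, k = ncol(nb), n = n,
                 in_ptr = as.integer(in_ptr), in_idx = as.integer(in_idx),
                 cell_ids = cell_ids),
            class = "knn_graph")
}

coords_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    if (!all(c("x", "y") %in% names(coords))) {
      stop("coordinate data frame needs columns 'x' and 'y'")
    }
    xy <- cbind(coords$x, coords$y)
    if ("cell_id" %in% names(coords)) rownames(xy) <- as.character(coords$cell_id)
  } else {
    xy <- as.matrix(coords)
    if (ncol(xy) != 2) stop("coordinates must have exactly two columns")
  }
  storage.mode(xy) <- "double"
  xy
}

#' @export
print.knn_graph <- function(x, ...) {
  cat("Directed kNN graph:", x$n, "cells, k =", x$k, "\n")
  invisible(x)
}

#' Directed neighbour-agreement count
#'
#' The Potts sufficient statistic: the number of ordered pairs (i, j) with j
#' among the k nearest neighbours of i and matching labels,
#' \eqn{\sum_i \sum_{j \in Nei_k(i)} I(C_i = C_j)}. Bounded by `n * k`, and
#' invariant under any relabelling bijection.
#'
#' @param labels integer label vector, one entry per cell.
#' @param graph a [knn_graph()].
#' @return A single non-negative integer.
#' @export
directed_agreement <- function(labels, graph) {
  stopifnot(inherits(graph, "knn_graph"))
  if (length(labels) != graph$n) {
    stop("labels has length ", length(labels), " but graph has ", graph$n,
         " cells")
  }
  agreement_count_cpp(as.integer(labels), graph$nb)
}

#' Export / import a kNN graph as an edge list
#'
#' Two-column delimited text (source, target), one row per directed edge,
#' for debugging and interoperability.
#'
#' @param graph a [knn_graph()].
#' @param path file path.
#' @return `write_graph_edges()` returns `path` invisibly;
#'   `read_graph_edges()` returns a `"knn_graph"`.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "knn_graph"))
  edges <- data.frame(source = rep(seq_len(graph$n), times = graph$k),
                      target = as.vector(graph$nb))
  edges <- edges[order(edges$source), ]
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_graph_edges
#' @export
read_graph_edges <- function(path) {
  edges <- readr::read_csv(path, col_types = "ii", progress = FALSE)
  n <- max(edges$source, edges$target)
  counts <- tabulate(edges$source, nbins = n)
  k <- unique(counts)
  if (length(k) != 1) stop("edge list is not a constant-degree kNN graph")
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) nb[i, ] <- edges$target[edges$source == i]
  new_knn_graph(nb)
}
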