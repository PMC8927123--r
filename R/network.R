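#' Weighted network
#'
#' A weighted, generically directed network represented by its dense
#' adjacency matrix.  The orientation convention is *row = receiver*:
#' `weights[i, j]` is the weight of the edge from node `j` into node `i`,
#' so the cluster in-degrees of a node are sums along its row.  All other
#' functions in the package inherit this convention.
#'
#' @param weights Square numeric matrix of edge weights.
#' @param labels Character vector of unique node identifiers, one per
#'   row/column.  Defaults to existing dimnames, or `"1".."N"`.
#' @param allow_self_loops Keep nonzero diagonal entries?  By default a
#'   nonzero diagonal is an error, matching the convention that the
#'   networks under study have no self-loops.
#'
#' @return An object of class `weighted_network` with elements `weights`
#'   (the `N x N` matrix, dimnames set to the labels), `labels` and
#'   `n_nodes`.
#' @examples
#' net <- weighted_network(matrix(c(0, 1, 2, 0), 2, 2), labels = c("a", "b"))
#' net$weights["a", "b"]  # weight of the edge b -> a
#' @export
weighted_network <- function(weights, labels = NULL, allow_self_loops = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("adjacency matrix must be square, got ", nrow(weights), " x ",
         ncol(weights))
  }
  if (!is.numeric(weights) || anyNA(weights)) {
    stop("adjacency matrix must be numeric with no missing values")
  }
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- rownames(weights) %||% as.character(seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("need ", n, " node labels, got ", length(labels))
  }
  if (anyDuplicated(labels)) {
    stop("node labels must be unique")
  }
  if (!allow_self_loops && any(diag(weights) != 0)) {
    stop("self-loops (nonzero diagonal) are rejected unless ",
         "allow_self_loops = TRUE")
  }
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, labels = labels, n_nodes = n),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  nnz <- sum(x$weights != 0)
  cat("Weighted network:", x$n_nodes, "nodes,", nnz, "nonzero edges\n")
  cat("  total weight:", format(sum(x$weights)), "\n")
  cat("  symmetric:", isSymmetric(unname(x$weights)), "\n")
  invisible(x)
}

#' @export
as.matrix.weighted_network <- function(x, ...) x$weights

# Accept either a weighted_network or a bare matrix; return the matrix.
as_adjacency <- function(net) {
  if (inherits(net, "weighted_network")) {
    net$weights
  } else if (is.matrix(net) && nrow(net) == ncol(net)) {
    net
  } else {
    stop("expected a weighted_network or a square matrix")
  }
}

# Number of nonzero off-diagonal entries.
n_edges <- function(net) {
  a <- as_adjacency(net)
  sum(a != 0) - sum(diag(a) != 0)
}
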