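#' Node partition
#'
#' An assignment of `N` nodes to `k` disjoint, non-empty clusters.
#' Partitions are stored in canonical form: clusters are numbered
#' `1..k` in order of first appearance along the node index, which makes
#' equality of partitions testable with [identical()] on the assignment.
#'
#' @param assignment Integer vector; `assignment[i]` is the cluster of
#'   node `i`.  Any coding is accepted and recoded canonically.
#' @return An object of class `node_partition` with elements
#'   `assignment` (canonical integer vector) and `k`.
#' @examples
#' p <- node_partition(c(2, 2, 7, 2, 7))
#' p$assignment  # 1 1 2 1 2
#' p$k           # 2
#' @export
node_partition <- function(assignment) {
  if (length(assignment) < 1L) stop("empty assignment")
  if (anyNA(assignment)) stop("assignment contains missing values")
  assignment <- canonical_assignment(assignment)
  structure(
    list(assignment = assignment, k = max(assignment)),
    class = "node_partition"
  )
}

# Renumber cluster ids 1..k by order of first appearance.
canonical_assignment <- function(assignment) {
  f <- match(assignment, unique(assignment))
  as.integer(f)
}

#' @export
print.node_partition <- function(x, ...) {
  cat("Partition of", length(x$assignment), "nodes into", x$k, "clusters\n")
  sizes <- tabulate(x$assignment, x$k)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Indicator matrix of a partition
#'
#' The `N x k` binary matrix `E` with `E[i, j] = 1` iff node `i` belongs
#' to cluster `j`.  Every row sums to 1 and every column to at least 1.
#'
#' @param part A [node_partition()].
#' @return Binary `N x k` matrix.
#' @export
indicator_matrix <- function(part) {
  part <- as_partition(part)
  n <- length(part$assignment)
  e <- matrix(0, n, part$k)
  e[cbind(seq_len(n), part$assignment)] <- 1
  e
}

#' Recover a partition from an indicator matrix
#'
#' Inverse of [indicator_matrix()]: each row must contain exactly one 1.
#'
#' @param e Binary `N x k` matrix.
#' @return A [node_partition()].
#' @export
partition_from_indicator <- function(e) {
  e <- as.matrix(e)
  if (any(e != 0 & e != 1) || any(rowSums(e) != 1)) {
    stop("indicator matrix must be binary with exactly one 1 per row")
  }
  if (any(colSums(e) < 1)) stop("indicator matrix has an empty cluster")
  node_partition(max.col(e))
}

# Coerce integer vectors (or partitions) to node_partition.
as_partition <- function(x) {
  if (inherits(x, "node_partition")) x else node_partition(x)
}

#' Extract clusters as a list of node indices
#'
#' @param part A [node_partition()].
#' @return List of length `k`; element `j` holds the indices of cluster `j`.
#' @export
cluster_members <- function(part) {
  part <- as_partition(part)
  split(seq_along(part$assignment), part$assignment)
}

#' Test whether two partitions are the same up to cluster relabeling
#'
#' @param p1,p2 Partitions of the same node set.
#' @return Logical scalar.
#' @export
same_partition <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  length(p1$assignment) == length(p2$assignment) &&
    identical(p1$assignment, p2$assignment)
}

#' Read a partition from a two-column TSV file
#'
#' Columns are node label and cluster id.  Rows are matched to `labels`
#' when given, otherwise file order is used.
#'
#' @param path File path.
#' @param labels Optional character vector giving the node order.
#' @return A [node_partition()].
#' @export
read_partition <- function(path, labels = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("label", "cluster"),
                           colClasses = c("character", "character"))
  if (!is.null(labels)) {
    idx <- match(labels, tab$label)
    if (anyNA(idx)) {
      stop("partition file is missing labels: ",
           paste(labels[is.na(idx)], collapse = ", "))
    }
    tab <- tab[idx, ]
  }
  node_partition(tab$cluster)
}

#' Write a partition to a two-column TSV file
#'
#' @param part A [node_partition()].
#' @param path File path.
#' @param labels Node labels; defaults to `"1".."N"`.
#' @export
write_partition <- function(part, path, labels = NULL) {
  part <- as_partition(part)
  labels <- labels %||% as.character(seq_along(part$assignment))
  utils::write.table(
    data.frame(label = labels, cluster = part$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
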