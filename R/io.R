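# Network file I/O: dense matrix, TSV edge list, Matrix Market.

#' Read a weighted network from a file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`dense`}{A full `N x N` matrix, whitespace- or comma-separated,
#'     one row per line.}
#'   \item{`edgelist`}{Tab/whitespace-separated lines `source target
#'     [weight]` (weight defaults to 1).  Lines starting with `#` are
#'     comments; a `# nodes:` comment, when present, fixes the node set
#'     and order (needed to round-trip isolated nodes).  Following the
#'     row-as-receiver convention, the weight of line `s t w` is stored
#'     at `weights[t, s]`.  Duplicate edges accumulate with a warning.}
#'   \item{`matrixmarket`}{Matrix Market coordinate or array format,
#'     general or symmetric, parsed by [Matrix::readMM()].}
#' }
#'
#' @param path File path.
#' @param format One of `"dense"`, `"edgelist"`, `"matrixmarket"`.
#' @param allow_self_loops Passed to [weighted_network()].
#' @return A [weighted_network()].
#' @export
read_network <- function(path,
                         format = c("dense", "edgelist", "matrixmarket"),
                         allow_self_loops = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    dense = read_dense(path, allow_self_loops),
    edgelist = read_edgelist(path, allow_self_loops),
    matrixmarket = read_mm(path, allow_self_loops)
  )
}

read_dense <- function(path, allow_self_loops) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric", comment.char = "#"),
    error = function(e) stop("cannot parse dense matrix file '", path,
                             "': ", conditionMessage(e))
  )
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop("dense matrix in '", path, "' is not square: ",
         nrow(m), " x ", ncol(m))
  }
  weighted_network(m, allow_self_loops = allow_self_loops)
}

read_edgelist <- function(path, allow_self_loops) {
  lines <- readLines(path)
  labels <- NULL
  hdr <- grep("^#\\s*nodes:", lines, value = TRUE)
  if (length(hdr) >= 1L) {
    labels <- strsplit(sub("^#\\s*nodes:\\s*", "", hdr[1L]), "[\t ]+")[[1L]]
    labels <- labels[nzchar(labels)]
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  src <- character(0); tgt <- character(0); w <- numeric(0)
  for (ii in seq_along(parts)) {
    p <- parts[[ii]]
    if (length(p) < 2L || length(p) > 3L) {
      stop("malformed edge list line ", rows[ii], " in '", path, "': '",
           lines[rows[ii]], "'")
    }
    wt <- if (length(p) == 3L) suppressWarnings(as.numeric(p[3L])) else 1.0
    if (is.na(wt)) {
      stop("non-numeric weight on line ", rows[ii], " in '", path, "'")
    }
    src <- c(src, p[1L]); tgt <- c(tgt, p[2L]); w <- c(w, wt)
  }
  if (is.null(labels)) labels <- unique(c(rbind(src, tgt)))
  if (length(labels) == 0L) stop("edge list '", path, "' defines no nodes")
  miss <- setdiff(c(src, tgt), labels)
  if (length(miss)) {
    stop("edge list '", path, "' uses nodes absent from its # nodes: ",
         "header: ", paste(unique(miss), collapse = ", "))
  }
  n <- length(labels)
  m <- matrix(0, n, n)
  # row = target (receiver), column = source
  ij <- cbind(match(tgt, labels), match(src, labels))
  if (anyDuplicated(ij)) {
    warning("duplicate edges in '", path, "'; weights accumulated")
  }
  for (e in seq_along(w)) m[ij[e, 1L], ij[e, 2L]] <- m[ij[e, 1L], ij[e, 2L]] + w[e]
  weighted_network(m, labels = labels, allow_self_loops = allow_self_loops)
}

read_mm <- function(path, allow_self_loops) {
  m <- tryCatch(as.matrix(Matrix::readMM(path)),
                error = function(e) stop("cannot parse Matrix Market file '",
                                         path, "': ", conditionMessage(e)))
  if (nrow(m) != ncol(m)) {
    stop("Matrix Market file '", path, "' is not square: ",
         nrow(m), " x ", ncol(m))
  }
  weighted_network(m, allow_self_loops = allow_self_loops)
}

#' Write a weighted network to a file
#'
#' Inverse of [read_network()]; a write/read round trip reproduces the
#' weights to full double precision and the labels exactly (dense and
#' Matrix Market files carry no labels, so default labels are assumed).
#'
#' @param net A [weighted_network()].
#' @param path File path.
#' @param format One of `"dense"`, `"edgelist"`, `"matrixmarket"`.
#' @export
write_network <- function(net,
                          path,
                          format = c("dense", "edgelist", "matrixmarket")) {
  format <- match.arg(format)
  a <- as_adjacency(net)
  labels <- if (inherits(net, "weighted_network")) net$labels
            else as.character(seq_len(nrow(a)))
  switch(format,
    dense = {
      utils::write.table(format(a, digits = 17, scientific = TRUE,
                                trim = TRUE),
                         path, sep = " ", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    },
    edgelist = {
      nz <- which(a != 0, arr.ind = TRUE)
      lines <- c(
        "# source\ttarget\tweight",
        paste0("# nodes: ", paste(labels, collapse = "\t")),
        if (nrow(nz)) {
          # row index is the receiver, so it is the target column
          paste(labels[nz[, 2L]], labels[nz[, 1L]],
                format(a[nz], digits = 17, scientific = TRUE, trim = TRUE),
                sep = "\t")
        }
      )
      writeLines(lines, path)
    },
    matrixmarket = {
      Matrix::writeMM(methods::as(Matrix::Matrix(a, sparse = TRUE),
                                  "generalMatrix"), path)
    }
  )
  invisible(path)
}
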