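#' Construct a weighted connectome
#'
#' A connectome is a symmetric, non-negative weighted adjacency matrix with a
#' zero diagonal and named nodes. Edge weights are typically the product of
#' mean tract fractional anisotropy (FA) and streamline count (FN) between two
#' grey-matter regions.
#'
#' @param w square numeric matrix of edge weights.
#' @param labels character vector of node names; defaults to the row names of
#'   `w` or `n1..nN`.
#' @return An object of class `connectome` with elements `w` (the matrix,
#'   dimnames set to `labels`), `labels`, `N` (node count) and `V` (count of
#'   edges with positive weight).
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 5
#' connectome(w, labels = c("A", "B", "C"))
connectome <- function(w, labels = NULL) {
  if (!is.matrix(w) || !is.numeric(w)) format_error("`w` must be a numeric matrix.")
  if (nrow(w) != ncol(w)) format_error(sprintf(
    "adjacency must be square; got %d x %d.", nrow(w), ncol(w)))
  labels <- labels %||% rownames(w) %||% paste0("n", seq_len(nrow(w)))
  if (length(labels) != nrow(w)) format_error("`labels` length must equal node count.")
  if (anyDuplicated(labels)) format_error("node labels must be unique.")
  if (any(!is.finite(w))) validation_error("adjacency contains non-finite weights.")
  if (any(w < 0)) validation_error("adjacency contains negative weights.")
  asym <- max(abs(w - t(w)))
  if (asym > 1e-9) {
    validation_error(sprintf("adjacency is asymmetric (max |w_ij - w_ji| = %.3g).", asym))
  } else if (asym > 0) {
    warn("adjacency differs from its transpose by <= 1e-9; symmetrized by averaging.")
    w <- (w + t(w)) / 2
  }
  diag(w) <- 0
  dimnames(w) <- list(labels, labels)
  structure(
    list(w = w, labels = labels, N = nrow(w),
         V = sum(w[upper.tri(w)] > 0)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d edges (density %.3f)\n",
              x$N, x$V, x$V / (x$N * (x$N - 1) / 2)))
  invisible(x)
}

#' @export
as.matrix.connectome <- function(x, ...) x$w

# weight matrix of a connectome or thresholded graph
wadj <- function(x) {
  if (inherits(x, "connectome") || inherits(x, "thresholded_graph")) return(x$w)
  if (is.matrix(x)) return(x)
  abort("expected a connectome, thresholded_graph, or matrix.")
}

#' Load the AAL90 atlas table
#'
#' Ninety cerebral regions of the Automated Anatomical Labeling parcellation,
#' in standard index order (odd indices left hemisphere), shipped as a
#' plain-text fixture.
#'
#' @return A tibble with columns `index`, `abbrev` (e.g. `ORBinf.R`), `name`
#'   and `hemisphere`.
#' @export
#' @examples
#' aal90()
aal90 <- function() {
  path <- system.file("extdata", "aal90.csv", package = "melnet", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a weighted white-matter network from per-edge tract summaries
#'
#' Each tract record carries the mean fractional anisotropy `fa` and the
#' streamline count `fn` between two atlas regions; the edge weight is their
#' product, `w_ij = fa_ij * fn_ij`, mirrored across the diagonal. Region pairs
#' without a record get weight zero.
#'
#' @param edges data frame with columns `node_i`, `node_j`, `fa`, `fn`.
#' @param atlas atlas table as returned by [aal90()]; node order follows
#'   `atlas$index`.
#' @return A [connectome()] with `N = nrow(atlas)` nodes.
#' @export
#' @examples
#' atlas <- aal90()
#' edges <- tibble::tibble(node_i = "ORBinf.R", node_j = "CAU.R", fa = 0.5, fn = 10)
#' build_weighted_network(edges, atlas)
build_weighted_network <- function(edges, atlas = aal90()) {
  edges <- as_tibble(edges)
  need <- c("node_i", "node_j", "fa", "fn")
  if (!all(need %in% names(edges))) {
    format_error("`edges` must have columns node_i, node_j, fa, fn.")
  }
  labels <- atlas$abbrev
  bad <- setdiff(c(edges$node_i, edges$node_j), labels)
  if (length(bad)) lookup_error(sprintf(
    "unknown node label(s): %s", paste(unique(bad), collapse = ", ")))
  if (any(edges$node_i == edges$node_j)) validation_error("self-edges are not allowed.")
  if (any(edges$fa < 0 | edges$fa > 1)) validation_error("`fa` must lie in [0, 1].")
  if (any(edges$fn < 0 | edges$fn != round(edges$fn))) {
    validation_error("`fn` must be a non-negative integer streamline count.")
  }
  i <- match(edges$node_i, labels)
  j <- match(edges$node_j, labels)
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) format_error(sprintf(
    "duplicate tract record(s) for pair(s): %s",
    paste(unique(key[duplicated(key)]), collapse = "; ")))
  n <- length(labels)
  w <- matrix(0, n, n)
  w[cbind(i, j)] <- edges$fa * edges$fn
  w[cbind(j, i)] <- edges$fa * edges$fn
  connectome(w, labels)
}

#' Read and write adjacency matrices
#'
#' `write_adjacency()` stores a connectome as a delimited N x N text file with
#' no header; `read_adjacency()` is its inverse. Reading rejects non-square or
#' negative input; an input whose asymmetry is within `1e-9` is symmetrized by
#' averaging with a warning.
#'
#' @param path file path.
#' @param labels node labels to attach (defaults to the AAL90 abbreviations
#'   when the matrix is 90 x 90, `n1..nN` otherwise).
#' @param delim field delimiter, default `","`.
#' @return `read_adjacency()` returns a [connectome()]; `write_adjacency()`
#'   returns `path` invisibly.
#' @export
read_adjacency <- function(path, labels = NULL, delim = ",") {
  rows <- utils::read.table(path, sep = delim, header = FALSE,
                            colClasses = "numeric")
  w <- as.matrix(rows)
  if (nrow(w) != ncol(w)) format_error(sprintf(
    "adjacency file must be square; got %d x %d.", nrow(w), ncol(w)))
  if (is.null(labels) && nrow(w) == 90) labels <- aal90()$abbrev
  connectome(unname(w), labels)
}

#' @param conn a [connectome()].
#' @rdname read_adjacency
#' @export
write_adjacency <- function(conn, path, delim = ",") {
  stopifnot(inherits(conn, "connectome"))
  utils::write.table(conn$w, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
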