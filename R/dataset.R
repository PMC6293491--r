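#' Time-series expression dataset
#'
#' Container for multi-series (multi-perturbation) time-course expression
#' data: one or more independent time series measured over the same genes.
#' This mirrors the DREAM4 time-series layout, where several perturbation
#' experiments over the same network are stacked in one file.
#'
#' @param series a numeric matrix (time points x genes) for a single series,
#'   or a list of such matrices, all with the same column count and order.
#' @param genes character vector of gene identifiers; defaults to the column
#'   names of the first series, or `G1..GN` if unnamed.
#' @param times numeric vector (or list of vectors, one per series) of
#'   measurement times, strictly increasing within each series. Defaults to
#'   `0, 1, 2, ...` per series.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `genes` (character), `series` (list of numeric matrices) and `times`
#'   (list of numeric vectors).
#' @examples
#' m <- matrix(rnorm(42), nrow = 21, ncol = 2,
#'             dimnames = list(NULL, c("G1", "G2")))
#' ds <- expression_dataset(m)
#' ds
#' @export
expression_dataset <- function(series, genes = NULL, times = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (!is.list(series) || length(series) == 0L)
    stop("'series' must be a matrix or a non-empty list of matrices")
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  ncols <- vapply(series, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("all series must have the same number of genes (columns)")
  if (is.null(genes)) {
    genes <- colnames(series[[1L]])
    if (is.null(genes)) genes <- paste0("G", seq_len(ncols[1L]))
  }
  genes <- as.character(genes)
  if (length(genes) != ncols[1L])
    stop("length of 'genes' does not match the number of columns")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  series <- lapply(series, function(m) { colnames(m) <- genes; m })
  if (is.null(times)) {
    times <- lapply(series, function(m) seq_len(nrow(m)) - 1)
  } else {
    if (is.numeric(times)) times <- rep(list(times), length(series))
    if (length(times) != length(series))
      stop("'times' must supply one time vector per series")
  }
  for (i in seq_along(series)) {
    if (nrow(series[[i]]) < 2L)
      stop("series ", i, " has fewer than 2 time points")
    if (length(times[[i]]) != nrow(series[[i]]))
      stop("series ", i, ": time vector length does not match rows")
    if (any(diff(times[[i]]) <= 0))
      stop("series ", i, ": times must be strictly increasing")
    if (any(!is.finite(series[[i]])))
      stop("series ", i, " contains non-finite expression values")
  }
  structure(list(genes = genes, series = series, times = times),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  np <- vapply(x$series, nrow, integer(1))
  cat("Expression dataset: ", length(x$genes), " genes, ",
      length(x$series), " series (",
      paste(np, collapse = " + "), " = ", sum(np), " time points)\n",
      sep = "")
  cat("Genes: ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.expression_dataset <- function(x, ...) {
  do.call(rbind, x$series)
}

# Integer series label per pooled row, parallel to as.matrix().
series_labels <- function(ds) {
  rep(seq_along(ds$series), vapply(ds$series, nrow, integer(1)))
}

#' Directed gene network
#'
#' A digraph over named genes: edges are ordered (regulator, target) pairs,
#' no self-loops, no duplicates. Inferred networks additionally carry at
#' most one direction per unordered pair (mutual regulation is outside the
#' model). `known_absent` optionally records pairs a gold standard declares
#' as explicit non-edges.
#'
#' @param edges a two-column matrix or data frame (regulator, target), or
#'   NULL/empty for an edgeless network.
#' @param genes character vector of the gene universe; defaults to the
#'   genes appearing in `edges`.
#' @param known_absent optional two-column matrix/data frame of explicit
#'   non-edges (kept for audit; not used in scoring beyond TN membership).
#' @return An object of class `gene_network` with elements `genes`
#'   (character) and `edges` (data frame with columns `regulator`, `target`).
#' @examples
#' net <- gene_network(data.frame(regulator = "G1", target = "G2"),
#'                     genes = c("G1", "G2", "G3"))
#' net
#' @export
gene_network <- function(edges = NULL, genes = NULL, known_absent = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop("'edges' needs two columns (regulator, target)")
    edges <- data.frame(regulator = as.character(edges[[1L]]),
                        target = as.character(edges[[2L]]),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$regulator == edges$target))
    stop("self-loops are not allowed")
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  genes <- as.character(genes)
  missing <- setdiff(unique(c(edges$regulator, edges$target)), genes)
  if (length(missing))
    stop("edge genes absent from the gene universe: ",
         paste(missing, collapse = ", "))
  if (!is.null(known_absent) && NROW(known_absent) > 0L) {
    known_absent <- data.frame(regulator = as.character(known_absent[[1L]]),
                               target = as.character(known_absent[[2L]]),
                               stringsAsFactors = FALSE)
  } else known_absent <- NULL
  structure(list(genes = genes, edges = edges, known_absent = known_absent),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Directed gene network: ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) {
    shown <- utils::head(x$edges, 10)
    cat(paste0("  ", shown$regulator, " -> ", shown$target), sep = "\n")
    if (nrow(x$edges) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.gene_network <- function(x, ...) x$edges

# canonical ordered-pair keys for set operations
edge_keys <- function(net) paste(net$edges$regulator, net$edges$target,
                                 sep = "\r")
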