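#' Z-score discretization of expression profiles
#'
#' Each gene is binarized by its absolute standardized deviation: with
#' per-gene mean `mu` and standard deviation `sigma` taken over ALL time
#' points (series pooled), a time point scores symbol 1 when
#' `|x - mu| / sigma >= k` (an excursion from the gene's typical level in
#' either direction) and 0 otherwise.
#'
#' @param dataset an [expression_dataset] or numeric matrix
#'   (time points x genes).
#' @param k Z-score threshold (default 1.2).
#' @param sd_divisor `"n"` (population standard deviation, default) or
#'   `"n-1"` (sample); affects boundary points only.
#' @return Integer 0/1 matrix with the same dimensions and gene columns,
#'   carrying a `series` attribute (integer label per row) when built from
#'   an `expression_dataset`. Constant genes (`sigma = 0`) discretize to
#'   all zeros with a warning.
#' @examples
#' discretize_zscore(cbind(G1 = c(0, 0, 0, 10)), k = 1.2)
#' @export
discretize_zscore <- function(dataset, k = 1.2, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive number")
  is_ds <- inherits(dataset, "expression_dataset")
  m <- if (is_ds) as.matrix(dataset) else as.matrix(dataset)
  n <- nrow(m)
  out <- matrix(0L, n, ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    sig <- stats::sd(m[, j])
    if (sd_divisor == "n") sig <- sig * sqrt((n - 1) / n)
    if (!is.finite(sig) || sig == 0) {
      warning("gene ", colnames(m)[j] %||% j,
              " is constant; discretized to all zeros", call. = FALSE)
      next
    }
    out[, j] <- as.integer(abs(m[, j] - mu) / sig >= k)
  }
  attr(out, "series") <- if (is_ds) series_labels(dataset)
                         else rep(1L, n)
  attr(out, "k") <- k
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orient one skeleton edge
#'
#' Scores both directions of an undirected edge on the discretized data:
#' each direction combines the conditional relative average entropy
#' CRAE(X -> Y) with the time-lagged mutual information I_T(X -> Y), and
#' the edge is directed toward the larger sum. An exact tie on the sums is
#' resolved by the larger I_T; an exact tie on both falls back to
#' directing from the lexicographically smaller gene name to the larger,
#' and the record is flagged `"unresolved"`.
#'
#' @param x,y the gene names of the edge's endpoints.
#' @param disc discretized matrix from [discretize_zscore()] (0/1 symbols,
#'   `series` attribute respected for the lagged MI).
#' @param tdelay regulation lag in sampling intervals (default 1).
#' @param base logarithm base shared by CRAE's entropies and I_T
#'   (default 2). CRAE is a dimensionless ratio while I_T is an entropy in
#'   log units, so the base can move near-tie decisions; it is a single
#'   knob on purpose.
#' @return One-row data frame: the four quantities, both direction sums,
#'   `regulator`, `target`, and the `rule` that decided
#'   (`"sum"`, `"it_tiebreak"` or `"unresolved"`).
#' @export
orient_edge <- function(x, y, disc, tdelay = 1, base = 2) {
  genes <- colnames(disc)
  if (!(x %in% genes) || !(y %in% genes))
    stop("edge endpoints not found in the discretized data")
  series <- attr(disc, "series") %||% rep(1L, nrow(disc))
  dx <- disc[, x]
  dy <- disc[, y]
  crae_xy <- crae(dx, dy, base)
  crae_yx <- crae(dy, dx, base)
  it_xy <- mi_lagged(dx, dy, series, tdelay, base)
  it_yx <- mi_lagged(dy, dx, series, tdelay, base)
  s_xy <- crae_xy + it_xy
  s_yx <- crae_yx + it_yx
  if (s_xy > s_yx) {
    reg <- x; tgt <- y; rule <- "sum"
  } else if (s_xy < s_yx) {
    reg <- y; tgt <- x; rule <- "sum"
  } else if (it_xy > it_yx) {
    reg <- x; tgt <- y; rule <- "it_tiebreak"
  } else if (it_xy < it_yx) {
    reg <- y; tgt <- x; rule <- "it_tiebreak"
  } else {
    reg <- min(x, y); tgt <- max(x, y); rule <- "unresolved"
  }
  data.frame(gene_a = x, gene_b = y,
             crae_ab = crae_xy, crae_ba = crae_yx,
             it_ab = it_xy, it_ba = it_yx,
             sum_ab = s_xy, sum_ba = s_yx,
             regulator = reg, target = tgt, rule = rule,
             stringsAsFactors = FALSE)
}

#' Orient every skeleton edge
#'
#' Applies [orient_edge()] to each undirected edge, yielding a directed
#' network with exactly one directed edge per skeleton edge: no
#' self-loops, no mutual (bidirectional) regulation.
#'
#' @param skel a `skeleton`.
#' @param disc discretized matrix covering all skeleton genes.
#' @inheritParams orient_edge
#' @return A [gene_network] whose `orientation` attribute holds the full
#'   per-edge audit records.
#' @export
orient_edges <- function(skel, disc, tdelay = 1, base = 2) {
  edges <- skel$edges
  if (nrow(edges) == 0L) {
    net <- gene_network(NULL, genes = skel$genes)
    attr(net, "orientation") <- data.frame()
    return(net)
  }
  recs <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i)
    orient_edge(edges$gene_a[i], edges$gene_b[i], disc,
                tdelay = tdelay, base = base)))
  recs$mic <- edges$score
  net <- gene_network(recs[, c("regulator", "target")], genes = skel$genes)
  attr(net, "orientation") <- recs
  net
}
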