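#' Confusion counts of a predicted network against a gold standard
#'
#' Counts over the ordered gene pairs (x, y), x != y, of the gene
#' universe: a pair is a true positive if the directed edge is in both
#' networks, a false positive if only predicted, a false negative if only
#' in the gold standard, and a true negative otherwise. A predicted edge
#' with reversed direction therefore contributes one FP (its own ordered
#' pair) and one FN (the gold pair). The negative universe is the
#' N(N-1) ordered non-self pairs: neither network may contain self-loops,
#' and this convention is what the accuracy denominator uses.
#'
#' With `directed = FALSE` both networks are collapsed to undirected edge
#' sets and counts are over the N(N-1)/2 unordered pairs (useful for
#' scoring the skeleton alone).
#'
#' @param predicted,gold [gene_network] objects over `genes`.
#' @param genes gene universe; defaults to the union of both networks'
#'   gene sets. Edges naming genes outside the universe are an error.
#' @param directed score directions (default) or undirected adjacency.
#' @return List of class `confusion` with integer `tp`, `fp`, `tn`, `fn`.
#' @examples
#' gold <- gene_network(data.frame(r = c("A", "B"), t = c("B", "C")),
#'                      genes = c("A", "B", "C"))
#' network_confusion(gold, gold)  # tp = 2, tn = 4
#' @export
network_confusion <- function(predicted, gold, genes = NULL,
                              directed = TRUE) {
  if (is.null(genes)) genes <- sort(union(predicted$genes, gold$genes))
  for (nm in c("predicted", "gold")) {
    net <- if (nm == "predicted") predicted else gold
    bad <- setdiff(unique(c(net$edges$regulator, net$edges$target)), genes)
    if (length(bad))
      stop(nm, " network names genes outside the universe: ",
           paste(bad, collapse = ", "))
  }
  pk <- edge_keys(predicted)
  gk <- edge_keys(gold)
  if (!directed) {
    pk <- unique(.pair_key(predicted$edges$regulator,
                           predicted$edges$target))
    gk <- unique(.pair_key(gold$edges$regulator, gold$edges$target))
  }
  n <- length(genes)
  universe <- if (directed) n * (n - 1L) else n * (n - 1L) %/% 2L
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(universe - tp - fp - fn),
                 fn = as.integer(fn), n_genes = length(genes),
                 directed = directed),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("Confusion over ", if (x$directed) "ordered" else "unordered",
      " gene pairs (", x$n_genes, " genes): TP=", x$tp, " FP=", x$fp,
      " TN=", x$tn, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Network-quality metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, F-score `2PR/(P+R)` and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric with a zero denominator is reported as 0 and listed in the
#' `undefined` attribute (the usual convention; MCC is 0 whenever a
#' marginal is empty).
#'
#' @param x a `confusion` object (or list with `tp`, `fp`, `tn`, `fn`).
#' @return Named numeric vector `precision`, `recall`, `acc`, `f_score`,
#'   `mcc`, with attribute `undefined` naming zero-denominator metrics.
#' @examples
#' network_metrics(list(tp = 2, fp = 1, tn = 5, fn = 2))
#' @export
network_metrics <- function(x) {
  tp <- as.numeric(x$tp); fp <- as.numeric(x$fp)
  tn <- as.numeric(x$tn); fn <- as.numeric(x$fn)
  if (min(tp, fp, tn, fn) < 0) stop("negative confusion counts")
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  acc <- safe(tp + tn, tp + fp + tn + fn, "acc")
  f <- safe(2 * precision * recall, precision + recall, "f_score")
  mcc <- safe(tp * tn - fp * fn,
              sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)), "mcc")
  out <- c(precision = precision, recall = recall, acc = acc,
           f_score = f, mcc = mcc)
  attr(out, "undefined") <- undef
  out
}

#' Score a predicted network against a gold standard
#'
#' Convenience wrapper: [network_confusion()] followed by
#' [network_metrics()].
#'
#' @inheritParams network_confusion
#' @return List with elements `confusion` and `metrics`.
#' @export
evaluate_network <- function(predicted, gold, genes = NULL,
                             directed = TRUE) {
  cc <- network_confusion(predicted, gold, genes, directed)
  list(confusion = cc, metrics = network_metrics(cc))
}
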