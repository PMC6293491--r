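#' Infer a directed gene regulatory network from time-series expression
#'
#' Runs the full two-phase inference. Phase one scores every gene pair
#' with the maximal information coefficient ([mic_matrix()]), keeps pairs
#' scoring at least `theta` ([build_skeleton()]), and deletes indirect
#' triangle edges whose Gaussian conditional mutual information given the
#' third gene is below `cmi_epsilon` ([prune_skeleton()]). Phase two
#' binarizes expression by the Z-score rule with threshold `k`
#' ([discretize_zscore()]) and directs each surviving edge by comparing
#' conditional relative average entropy plus time-lagged mutual
#' information in the two candidate directions ([orient_edges()]).
#'
#' @param data an [expression_dataset], or a numeric matrix
#'   (time points x genes) treated as a single series.
#' @param theta MIC threshold for skeleton edges. Defaults to 0.43 for
#'   networks of at most 20 genes and 0.15 for larger ones (the settings
#'   found to work well on the 10-gene and 100-gene benchmarks); a
#'   message recommends sweeping it on new data.
#' @param k Z-score discretization threshold (default 1.2).
#' @param tdelay regulation lag for the time-lagged MI, in sampling
#'   intervals (default 1).
#' @param alpha MIC grid-budget exponent, `B(n) = n^alpha` (default 0.6).
#' @param cmi_epsilon triangle-pruning CMI threshold in nats
#'   (default 0.01).
#' @param base logarithm base for the orientation quantities (default 2).
#' @param prune run the triangle-pruning step (default TRUE).
#' @param iterate_pruning iterate pruning to a fixpoint (default FALSE:
#'   one pass).
#' @param exact_limit exhaustive-search budget of the MIC optimizer.
#' @return Object of class `micnet`: list with the `config` used, the
#'   MIC score matrix `mic`, the pre- and post-pruning `skeleton`, the
#'   `pruned` edge audit, the per-edge `orientation` records, and the
#'   inferred [gene_network] in `network`.
#' @examples
#' truth <- sim_network(10, 15, seed = 7)
#' ds <- sim_expression(truth, seed = 7)
#' fit <- micnet(ds)
#' fit
#' evaluate_network(fit$network, truth)$metrics
#' @export
micnet <- function(data, theta = NULL, k = 1.2, tdelay = 1, alpha = 0.6,
                   cmi_epsilon = 0.01, base = 2, prune = TRUE,
                   iterate_pruning = FALSE, exact_limit = 200) {
  ds <- if (inherits(data, "expression_dataset")) data
        else expression_dataset(as.matrix(data))
  if (is.null(theta)) {
    theta <- if (length(ds$genes) <= 20L) 0.43 else 0.15
    message("theta not supplied: using ", theta, " (",
            length(ds$genes), " genes); consider sweeping theta on new data")
  }
  scores <- mic_matrix(ds, alpha = alpha, exact_limit = exact_limit)
  skel0 <- build_skeleton(scores, theta)
  if (prune) {
    skel <- prune_skeleton(skel0, ds, cmi_epsilon = cmi_epsilon,
                           iterate = iterate_pruning)
    pruned <- attr(skel, "pruned")
  } else {
    skel <- skel0
    pruned <- data.frame()
  }
  disc <- discretize_zscore(ds, k = k)
  net <- orient_edges(skel, disc, tdelay = tdelay, base = base)
  structure(list(
    call = match.call(),
    config = list(theta = theta, k = k, tdelay = tdelay, alpha = alpha,
                  cmi_epsilon = cmi_epsilon, base = base, prune = prune,
                  iterate_pruning = iterate_pruning,
                  exact_limit = exact_limit),
    genes = ds$genes,
    n_series = length(ds$series),
    n_points = sum(vapply(ds$series, nrow, integer(1))),
    mic = scores,
    skeleton_raw = skel0,
    skeleton = skel,
    pruned = pruned,
    orientation = attr(net, "orientation"),
    network = net), class = "micnet")
}

#' @export
print.micnet <- function(x, ...) {
  cat("Inferred gene regulatory network (MIC skeleton + entropy",
      "orientation)\n")
  cat("  ", length(x$genes), " genes, ", x$n_series, " series, ",
      x$n_points, " time points\n", sep = "")
  cat("  theta = ", format(x$config$theta), ", k = ",
      format(x$config$k), ", tdelay = ", x$config$tdelay, "\n", sep = "")
  cat("  skeleton: ", nrow(x$skeleton_raw$edges), " edges, ",
      NROW(x$pruned), " pruned as indirect\n", sep = "")
  cat("  network:  ", nrow(x$network$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' @export
summary.micnet <- function(object, ...) {
  mics <- object$mic[upper.tri(object$mic)]
  structure(list(fit = object,
                 mic_range = range(mics),
                 mic_above_theta = sum(mics >= object$config$theta),
                 n_pairs = length(mics),
                 rules = table(object$orientation$rule)),
            class = "summary.micnet")
}

#' @export
print.summary.micnet <- function(x, ...) {
  print(x$fit)
  cat("  MIC over ", x$n_pairs, " pairs: range [",
      format(x$mic_range[1], digits = 3), ", ",
      format(x$mic_range[2], digits = 3), "], ",
      x$mic_above_theta, " >= theta\n", sep = "")
  if (length(x$rules)) {
    cat("  orientation rules: ",
        paste(names(x$rules), as.integer(x$rules), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.micnet <- function(object, ...) object$mic

#' Plot an inferred network
#'
#' Genes on a circle, directed edges as arrows; pruned skeleton edges can
#' be overlaid dashed.
#'
#' @param x a `micnet` fit.
#' @param show_pruned overlay edges removed by triangle pruning
#'   (default FALSE).
#' @param ... passed to [graphics::arrows()].
#' @export
plot.micnet <- function(x, show_pruned = FALSE, ...) {
  g <- x$genes
  n <- length(g)
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", pch = 21,
                 bg = "grey85", cex = 2.4)
  graphics::text(1.15 * px, 1.15 * py, g, cex = 0.8)
  draw <- function(a, b, lty, col) {
    i <- match(a, g); j <- match(b, g)
    sh <- 0.09  # pull arrow endpoints off the node circles
    dx <- px[j] - px[i]; dy <- py[j] - py[i]
    len <- sqrt(dx^2 + dy^2)
    graphics::arrows(px[i] + sh * dx / len, py[i] + sh * dy / len,
                     px[j] - sh * dx / len, py[j] - sh * dy / len,
                     length = 0.08, lty = lty, col = col, ...)
  }
  e <- x$network$edges
  for (r in seq_len(nrow(e))) draw(e$regulator[r], e$target[r], 1, "black")
  if (show_pruned && NROW(x$pruned)) {
    for (r in seq_len(nrow(x$pruned)))
      draw(x$pruned$gene_a[r], x$pruned$gene_b[r], 2, "grey60")
  }
  invisible(x)
}
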