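#' Undirected association skeleton
#'
#' Phase one of the inference: threshold the pairwise MIC table to obtain
#' an undirected graph, then delete indirect edges inside triangles whose
#' conditional mutual information given the third gene vanishes.
#'
#' @name skeleton
NULL

# canonical unordered pair key (lexicographic)
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Rank gene pairs by association score
#'
#' All unordered gene pairs sorted by descending MIC score, ties broken by
#' lexicographic gene-pair order so the list is reproducible. Kept mainly
#' for audit: thresholding is order-independent.
#'
#' @param scores symmetric MIC matrix from [mic_matrix()].
#' @return Data frame with columns `gene_a`, `gene_b`, `score`, in rank
#'   order over all N(N-1)/2 pairs.
#' @export
rank_pairs <- function(scores) {
  genes <- rownames(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  df <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                   score = scores[idx], stringsAsFactors = FALSE)
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the thresholded skeleton
#'
#' Retains exactly the unordered pairs whose MIC score is at least
#' `theta`.
#'
#' @inheritParams rank_pairs
#' @param theta MIC threshold in `[0, 1]`.
#' @return An object of class `skeleton`: list with `genes` and an edge
#'   data frame (`gene_a`, `gene_b`, `score`), pairs in the ranked order.
#' @examples
#' s <- matrix(c(NA, .9, .5, .9, NA, .2, .5, .2, NA), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' build_skeleton(s, theta = 0.43)   # edges A-B and A-C
#' @export
build_skeleton <- function(scores, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("'theta' must be a single non-negative number")
  ranked <- rank_pairs(scores)
  keep <- ranked[!is.na(ranked$score) & ranked$score >= theta, , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(genes = rownames(scores), edges = keep, theta = theta),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("Undirected skeleton: ", length(x$genes), " genes, ", nrow(x$edges),
      " edges (theta = ", format(x$theta), ")\n", sep = "")
  invisible(x)
}

# all triangles over the current edge set, vertices sorted, triangles in
# ascending lexicographic order
.triangles <- function(genes, keys) {
  genes <- sort(genes)
  out <- list()
  n <- length(genes)
  if (n < 3L) return(out)
  has <- function(a, b) .pair_key(a, b) %in% keys
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    if (!has(genes[i], genes[j])) next
    for (k in (j + 1L):n) {
      if (has(genes[i], genes[k]) && has(genes[j], genes[k]))
        out[[length(out) + 1L]] <- c(genes[i], genes[j], genes[k])
    }
  }
  out
}

#' Prune indirect triangle edges by conditional mutual information
#'
#' For every triangle X-Y-Z in the skeleton, the three Gaussian-covariance
#' CMIs I(X,Y|Z), I(X,Z|Y) and I(Y,Z|X) are computed on the raw profiles;
#' an edge whose CMI given the third vertex is at most `cmi_epsilon` is
#' indirect (the third gene explains the association) and is deleted.
#' Within a triangle the edge with the smallest CMI is tested first; once
#' an edge is deleted the triangle no longer exists, so at most one edge
#' per triangle is removed per pass. A single pass over the initial
#' triangle list is taken by default (`iterate = TRUE` repeats until no
#' deletion fires).
#'
#' @param skel a `skeleton` from [build_skeleton()].
#' @param dataset the [expression_dataset] (or pooled matrix) the skeleton
#'   was built from.
#' @param cmi_epsilon deletion threshold on the CMI, in nats
#'   (default 0.01): exact conditional independence is never attained in
#'   floating point.
#' @param iterate repeat passes until a fixpoint (default FALSE).
#' @return The pruned `skeleton`, with a `pruned` attribute: data frame of
#'   deleted edges with the conditioning gene and the CMI value.
#' @export
prune_skeleton <- function(skel, dataset, cmi_epsilon = 0.01,
                           iterate = FALSE) {
  m <- if (inherits(dataset, "expression_dataset")) as.matrix(dataset)
       else as.matrix(dataset)
  if (!all(skel$genes %in% colnames(m)))
    stop("dataset does not cover all skeleton genes")
  edges <- skel$edges
  keys <- .pair_key(edges$gene_a, edges$gene_b)
  dropped <- data.frame(gene_a = character(0), gene_b = character(0),
                        given = character(0), cmi = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    tris <- .triangles(unique(c(edges$gene_a, edges$gene_b)), keys)
    deleted_any <- FALSE
    for (tri in tris) {
      ek <- c(.pair_key(tri[2L], tri[3L]),  # conditioned on tri[1]
              .pair_key(tri[1L], tri[3L]),  # on tri[2]
              .pair_key(tri[1L], tri[2L]))  # on tri[3]
      if (!all(ek %in% keys)) next  # broken by an earlier deletion
      cmis <- c(cmi_gaussian(m[, tri[2L]], m[, tri[3L]], m[, tri[1L]]),
                cmi_gaussian(m[, tri[1L]], m[, tri[3L]], m[, tri[2L]]),
                cmi_gaussian(m[, tri[1L]], m[, tri[2L]], m[, tri[3L]]))
      w <- which.min(cmis)
      if (cmis[w] <= cmi_epsilon) {
        drop_pair <- switch(w, c(tri[2L], tri[3L]), c(tri[1L], tri[3L]),
                            c(tri[1L], tri[2L]))
        keep <- keys != ek[w]
        edges <- edges[keep, , drop = FALSE]
        keys <- keys[keep]
        dropped <- rbind(dropped, data.frame(
          gene_a = drop_pair[1L], gene_b = drop_pair[2L], given = tri[w],
          cmi = cmis[w], stringsAsFactors = FALSE))
        deleted_any <- TRUE
      }
    }
    if (!iterate || !deleted_any) break
  }
  rownames(edges) <- NULL
  out <- structure(list(genes = skel$genes, edges = edges,
                        theta = skel$theta), class = "skeleton")
  attr(out, "pruned") <- dropped
  out
}
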