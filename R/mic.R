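#' @useDynLib micnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# admissible column counts for a given row count under the grid budget
# B = n^alpha with strict ("xy < B") or non-strict comparison
.max_cols_for <- function(nrows, B, strict) {
  cmax <- floor(B / nrows + 1e-9)
  if (strict && cmax * nrows >= B - 1e-9) cmax <- cmax - 1L
  as.integer(cmax)
}

#' Mutual information of a gridded dataset
#'
#' Plug-in mutual information of the bin-index pair induced by an explicit
#' grid partition: `x` is binned at `x_cuts`, `y` at `y_cuts` (cells may be
#' empty; zero-probability cells contribute nothing).
#'
#' @param x,y numeric profiles of equal length.
#' @param x_cuts,y_cuts strictly increasing numeric cut points; values are
#'   assigned to bins by `findInterval`.
#' @param base logarithm base for the returned MI (default 2, bits).
#' @examples
#' x <- 1:6; y <- c(1, 1, 2, 2, 3, 3)
#' grid_mi(x, y, x_cuts = c(2.5, 4.5), y_cuts = c(1.5, 2.5))  # log2(3) bits
#' @export
grid_mi <- function(x, y, x_cuts, y_cuts, base = 2) {
  check_same_length(x, y)
  if (is.unsorted(x_cuts, strictly = TRUE) ||
      is.unsorted(y_cuts, strictly = TRUE))
    stop("cut points must be strictly increasing")
  mi_discrete(findInterval(x, x_cuts), findInterval(y, y_cuts), base)
}

#' Maximal grid mutual information for fixed grid dimensions
#'
#' The largest plug-in MI achievable by any rank-based grid with at most
#' `nx` column bins on `x` and `ny` row bins on `y`. One axis is searched
#' by exact dynamic programming; the other is enumerated exhaustively when
#' at most `exact_limit` rank-cut placements exist, and rank-equipartitioned
#' otherwise (the standard MIC search approximation). Both axis roles are
#' tried and the larger value returned.
#'
#' @inheritParams grid_mi
#' @param nx,ny grid dimensions, both at least 2.
#' @param exact_limit exhaustive-enumeration budget for the non-DP axis.
#' @return MI in units of `base`; at most `log(min(nx, ny), base)`.
#' @export
max_grid_mi <- function(x, y, nx, ny, base = 2, exact_limit = 200) {
  check_same_length(x, y)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L)
    stop("grid dimensions below 2 are uninformative; need nx >= 2 and ny >= 2")
  v <- max(.best_mi_profile(x, y, ny, nx, exact_limit)[nx],
           .best_mi_profile(y, x, nx, ny, exact_limit)[ny])
  max(v, 0) / log(base)
}

#' Maximal information coefficient
#'
#' MIC of two profiles: the maximum over all grid dimensions `(nx, ny)`
#' with `nx >= 2`, `ny >= 2` and `nx * ny < B(n)`, `B(n) = n^alpha`, of the
#' maximal grid MI normalized by `log(min(nx, ny))`. Lies in `[0, 1]`,
#' equals 1 on noiseless functional relationships given enough samples,
#' and is symmetric in its arguments. The search operates on ranks (ties
#' broken by original order), so MIC is invariant under strictly
#' increasing transformations of either profile.
#'
#' @inheritParams max_grid_mi
#' @param alpha grid-budget exponent, `B(n) = n^alpha` (default 0.6).
#' @param strict logical; require `nx * ny < B(n)` (default) rather than
#'   `<=`.
#' @return A value in `[0, 1]`. Constant (zero-variance) profiles give 0
#'   with a warning.
#' @examples
#' x <- seq(0, 1, length.out = 30)
#' mic(x, x^3)   # 1: noiseless monotone relationship
#' @export
mic <- function(x, y, alpha = 0.6, exact_limit = 200, strict = TRUE) {
  check_same_length(x, y)
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("profiles must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile: MIC defined as 0", call. = FALSE)
    return(0)
  }
  B <- n^alpha
  rmax <- .max_cols_for(2L, B, strict)
  if (rmax < 2L)
    stop("sample size ", n, " admits no grid under B(n) = n^", alpha,
         " (need n^alpha > 4)")
  best <- 0
  for (r in 2:rmax) {
    cmax <- .max_cols_for(r, B, strict)
    if (cmax < 2L) next
    p1 <- .best_mi_profile(x, y, r, cmax, exact_limit)
    p2 <- .best_mi_profile(y, x, r, cmax, exact_limit)
    for (cc in 2:cmax) {
      v <- max(p1[cc], p2[cc]) / log(min(cc, r))
      if (v > best) best <- v
    }
  }
  min(max(best, 0), 1)
}

#' Pairwise MIC score table
#'
#' Computes `mic()` for every unordered pair of genes on the raw
#' (undiscretized) profiles, with all independent series concatenated as
#' samples. Per-pair failures (e.g. a constant gene) score 0 with a
#' warning so the pipeline stays total.
#'
#' @param dataset an [expression_dataset], or a numeric matrix
#'   (time points x genes).
#' @inheritParams mic
#' @return Symmetric numeric matrix of MIC scores with gene dimnames;
#'   the diagonal is `NA` (self-association is not defined here).
#' @export
mic_matrix <- function(dataset, alpha = 0.6, exact_limit = 200,
                       strict = TRUE) {
  m <- if (inherits(dataset, "expression_dataset")) as.matrix(dataset)
       else as.matrix(dataset)
  if (ncol(m) < 2L) stop("need at least 2 genes")
  if (nrow(m) < 4L) stop("need at least 4 time points")
  genes <- colnames(m)
  if (is.null(genes)) genes <- paste0("G", seq_len(ncol(m)))
  k <- ncol(m)
  s <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      v <- tryCatch(mic(m[, i], m[, j], alpha = alpha,
                        exact_limit = exact_limit, strict = strict),
                    error = function(e) {
                      warning("MIC(", genes[i], ", ", genes[j],
                              ") failed (", conditionMessage(e),
                              "); scored 0", call. = FALSE)
                      0
                    })
      s[i, j] <- s[j, i] <- v
    }
  }
  s
}
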