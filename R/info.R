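#' Information-theoretic primitives
#'
#' Plug-in (empirical) entropy, joint/conditional entropy and mutual
#' information for discrete profiles, Gaussian-covariance estimators of
#' entropy, mutual information and conditional mutual information for
#' continuous profiles, the conditional relative average entropy used to
#' orient regulatory edges, and time-lagged mutual information for
#' detecting delayed regulation.
#'
#' Discrete quantities are reported in the units of `base` (default
#' `base = 2`, bits); the Gaussian-covariance estimators are in nats, as
#' their closed forms are naturally expressed in natural logarithms. All
#' comparisons inside the inference pipeline are order-based, so the unit
#' choice does not alter inferred networks, only reported magnitudes.
#'
#' @name info-theory
NULL

# empirical probabilities of a discrete vector (as a factor of its values)
.freqs <- function(x) {
  tabulate(match(x, unique(x))) / length(x)
}

plogp_sum <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

check_same_length <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles must have the same length (", length(x), " vs ",
         length(y), ")")
}

#' Entropy of a discrete profile
#'
#' Plug-in Shannon entropy \eqn{H(X) = -\sum_x p(x) \log p(x)} with
#' empirical symbol frequencies.
#'
#' @param x vector of discrete symbols (any atomic type).
#' @param base logarithm base; 2 gives bits, `exp(1)` gives nats.
#' @return Non-negative entropy, at most `log(alphabet size, base)`.
#' @examples
#' entropy_discrete(c(0, 1, 0, 1))      # 1 bit
#' entropy_discrete(c(0, 0, 0, 1))      # 0.811 bits
#' @export
entropy_discrete <- function(x, base = 2) {
  if (length(x) == 0L) stop("empty profile")
  plogp_sum(.freqs(x), base)
}

#' Joint entropy of two discrete profiles
#'
#' \eqn{H(X,Y) = -\sum_{x,y} p(x,y) \log p(x,y)} with empirical joint
#' frequencies over paired observations.
#'
#' @inheritParams entropy_discrete
#' @param y second profile, same length as `x`.
#' @export
joint_entropy_discrete <- function(x, y, base = 2) {
  check_same_length(x, y)
  if (length(x) == 0L) stop("empty profile")
  plogp_sum(.freqs(paste(x, y, sep = "\r")), base)
}

#' Conditional entropy H(Y | X)
#'
#' Computed through the chain identity `H(Y|X) = H(X,Y) - H(X)`, which is
#' exact for plug-in estimates.
#'
#' @param y target profile.
#' @param x conditioning profile, same length.
#' @inheritParams entropy_discrete
#' @export
cond_entropy_discrete <- function(y, x, base = 2) {
  check_same_length(x, y)
  h <- joint_entropy_discrete(x, y, base) - entropy_discrete(x, base)
  max(h, 0)
}

#' Mutual information of two discrete profiles
#'
#' Plug-in mutual information `I(X,Y) = H(X) + H(Y) - H(X,Y)`.
#'
#' @inheritParams joint_entropy_discrete
#' @return Non-negative (up to rounding); symmetric in its arguments.
#' @examples
#' mi_discrete(c(0, 0, 0, 1), c(0, 0, 1, 1))  # 0.311 bits
#' @export
mi_discrete <- function(x, y, base = 2) {
  check_same_length(x, y)
  entropy_discrete(x, base) + entropy_discrete(y, base) -
    joint_entropy_discrete(x, y, base)
}

# ---- Gaussian-covariance estimators (nats) ---------------------------------

# log-determinant of the sample covariance of the columns of m, with the
# singularity policy: determinants below `clamp` are clamped (warning),
# keeping the pipeline total where the closed form is undefined.
.logdet_cov <- function(m, clamp = getOption("micnet.det_clamp", 1e-12)) {
  if (nrow(m) < 2L) stop("need at least 2 samples to estimate a covariance")
  d <- det(stats::cov(m))
  if (!is.finite(d) || d <= clamp) {
    warning("near-singular covariance (det = ", format(d),
            "); clamped to ", format(clamp), call. = FALSE)
    d <- clamp
  }
  log(d)
}

#' Gaussian-covariance entropy
#'
#' Differential entropy of an m-dimensional Gaussian with the sample
#' covariance C of the input profiles:
#' \eqn{H = \frac{1}{2}\log((2\pi e)^m |C|)} (nats). `m` is the number of
#' profiles supplied (1 for a single gene, 2 for a pair, ...).
#'
#' @param x numeric vector (one profile) or matrix with one profile per
#'   column.
#' @return Entropy in nats. Near-singular covariances (determinant below
#'   `getOption("micnet.det_clamp", 1e-12)`) are clamped with a warning.
#' @examples
#' z <- scale(rnorm(100))  # unit sample variance
#' entropy_gaussian(z)     # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
#' @export
entropy_gaussian <- function(x) {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  k <- ncol(m)
  0.5 * (k * log(2 * pi * exp(1)) + .logdet_cov(m))
}

#' Gaussian-covariance mutual information
#'
#' \eqn{I(X,Y) = \frac{1}{2}\log\frac{|C(X)||C(Y)|}{|C(X,Y)|}} (nats),
#' which for a sample correlation rho equals `-0.5 * log(1 - rho^2)`.
#'
#' @param x,y numeric profiles of equal length (>= 3).
#' @export
mi_gaussian <- function(x, y) {
  check_same_length(x, y)
  if (length(x) < 3L) stop("need at least 3 samples")
  v <- 0.5 * (.logdet_cov(cbind(x)) + .logdet_cov(cbind(y)) -
                .logdet_cov(cbind(x, y)))
  max(v, 0)
}

#' Gaussian-covariance conditional mutual information
#'
#' \eqn{I(X,Y|Z) = \frac{1}{2}\log\frac{|C(X,Z)||C(Y,Z)|}{|C(Z)||C(X,Y,Z)|}}
#' (nats). Within a triangle of associated genes, a near-zero value for
#' I(Y,Z|X) indicates the Y-Z edge is indirect (explained by X).
#'
#' @param x,y numeric profiles whose conditional dependence is measured.
#' @param z conditioning profile, same length (>= 4).
#' @export
cmi_gaussian <- function(x, y, z) {
  check_same_length(x, y)
  check_same_length(x, z)
  if (length(x) < 4L) stop("need at least 4 samples")
  v <- 0.5 * (.logdet_cov(cbind(x, z)) + .logdet_cov(cbind(y, z)) -
                .logdet_cov(cbind(z)) - .logdet_cov(cbind(x, y, z)))
  max(v, 0)
}

# ---- orientation quantities ------------------------------------------------

#' Conditional relative average entropy, CRAE(X -> Y)
#'
#' \eqn{CRAE(X \to Y) = H(Y|X) / (H(Y)\,|Y|)} where `|Y|` is the number of
#' distinct symbols observed in the target profile. A dimensionless ratio
#' in `[0, 1/|Y|]`: 0 when the regulator determines the target, `1/|Y|`
#' when they are independent.
#'
#' A constant target (`H(Y) = 0`) also has `H(Y|X) = 0`; the ratio is
#' taken as 0 in that limit so an uninformative constant gene never
#' attracts an incoming edge under the orientation rule (which directs the
#' edge toward the larger combined score).
#'
#' @param x regulator profile (discrete symbols).
#' @param y target profile (discrete symbols), same length.
#' @inheritParams entropy_discrete
#' @examples
#' crae(c(0, 0, 1, 1), c(0, 1, 1, 1))  # 0.308
#' @export
crae <- function(x, y, base = 2) {
  check_same_length(x, y)
  hy <- entropy_discrete(y, base)
  if (hy == 0) return(0)
  ny <- length(unique(y))
  cond_entropy_discrete(y, x, base) / (hy * ny)
}

#' Time-lagged mutual information, I_T(X -> Y)
#'
#' Mutual information between the source truncated to its first `T - tdelay`
#' points and the target shifted to its last `T - tdelay` points, capturing
#' regulation with a delay of `tdelay` sampling intervals. Directional:
#' `mi_lagged(x, y)` need not equal `mi_lagged(y, x)`.
#'
#' With multiple independent series, the lagged pairs are formed within
#' each series and pooled into a single contingency before the plug-in MI
#' is taken: lagging across a series boundary would pair unrelated time
#' points from different perturbation experiments.
#'
#' @param x source profile (discrete symbols).
#' @param y target profile, same length and series structure.
#' @param series optional integer/factor vector assigning each time point
#'   to an independent series; NULL treats the whole profile as one series.
#' @param tdelay non-negative integer lag in sampling intervals (default 1);
#'   `tdelay = 0` reduces to plain `mi_discrete`.
#' @inheritParams entropy_discrete
#' @export
mi_lagged <- function(x, y, series = NULL, tdelay = 1, base = 2) {
  check_same_length(x, y)
  if (is.null(series)) series <- rep(1L, length(x))
  if (length(series) != length(x))
    stop("'series' must be parallel to the profiles")
  tdelay <- as.integer(tdelay)
  if (tdelay < 0L) stop("'tdelay' must be non-negative")
  idx <- split(seq_along(x), series)
  if (tdelay >= min(lengths(idx)))
    stop("'tdelay' (", tdelay, ") must be smaller than the shortest series")
  src <- tgt <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    n <- length(ii)
    src[[i]] <- x[ii[seq_len(n - tdelay)]]
    tgt[[i]] <- y[ii[seq_len(n - tdelay) + tdelay]]
  }
  mi_discrete(unlist(src), unlist(tgt), base)
}
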