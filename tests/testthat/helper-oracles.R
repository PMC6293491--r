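# Independent oracles and small simulators shared across tests.

# Brute-force maximal grid MI: enumerate every placement of up to nx-1
# rank cuts on x and ny-1 on y (ranks tie-broken by original order, the
# same convention the package documents) and take the best plug-in MI.
# Exponential; only for small n.
brute_grid_mi <- function(x, y, nx, ny, base = 2) {
  n <- length(x)
  rx <- order(order(x, seq_along(x)))
  ry <- order(order(y, seq_along(y)))
  lab <- function(rank_pos, cuts) findInterval(rank_pos, cuts + 0.5)
  best <- 0
  for (kx in 1:(nx - 1)) for (ky in 1:(ny - 1)) {
    for (a in utils::combn(n - 1, kx, simplify = FALSE))
      for (b in utils::combn(n - 1, ky, simplify = FALSE)) {
        v <- mi_discrete(lab(rx, a), lab(ry, b), base)
        if (v > best) best <- v
      }
  }
  best
}

# Brute-force MIC for small n: loop admissible grids explicitly.
brute_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- n^alpha
  best <- 0
  for (nx in 2:floor(B / 2)) for (ny in 2:floor(B / 2)) {
    if (nx * ny >= B) next
    v <- brute_grid_mi(x, y, nx, ny, base = 2) / log2(min(nx, ny))
    if (v > best) best <- v
  }
  best
}

# Pair-enumeration confusion oracle: walk every ordered non-self pair.
brute_confusion <- function(predicted, gold, genes) {
  pk <- paste(predicted$edges$regulator, predicted$edges$target)
  gk <- paste(gold$edges$regulator, gold$edges$target)
  tp <- fp <- tn <- fn <- 0L
  for (a in genes) for (b in genes) {
    if (a == b) next
    k <- paste(a, b)
    inp <- k %in% pk; ing <- k %in% gk
    if (inp && ing) tp <- tp + 1L
    else if (inp) fp <- fp + 1L
    else if (ing) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Static first-order chain X -> Y -> Z: instantaneous linear links, so
# X and Z are conditionally independent given Y by construction.
static_chain <- function(n = 105, noise = 0.3, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- x + rnorm(n, 0, noise)
  z <- y + rnorm(n, 0, noise)
  cbind(G1 = x, G2 = y, G3 = z)
}

# Two-gene network with its lagged simulation, for orientation tests.
lagged_pair <- function(seed, ...) {
  net <- gene_network(data.frame(regulator = "G1", target = "G2"),
                      genes = c("G1", "G2"))
  sim_expression(net, seed = seed, ...)
}

# Random directed network in the inference output space (via the
# package generator, unseeded: caller controls the RNG stream).
null_median_mcc <- function(truth, n_edges, genes, B = 1000) {
  meds <- numeric(B)
  for (b in seq_len(B)) {
    rn <- sim_network(length(genes), n_edges)
    meds[b] <- network_metrics(network_confusion(rn, truth, genes))[["mcc"]]
  }
  stats::median(meds)
}
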