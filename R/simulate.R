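#' Synthetic benchmark generator
#'
#' Seeded generation of ground-truth regulatory networks and time-series
#' expression with lagged regulation, so the full inference pipeline can
#' be exercised and scored without external benchmark downloads. The
#' default geometry mirrors the 10-gene multi-perturbation benchmarks:
#' 5 independent series of 21 time points (105 samples).
#'
#' @name synthetic
NULL

# run code under a local, seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Sample a random ground-truth network
#'
#' Draws a random DAG: a random topological order over the genes, then
#' `n_edges` edges sampled uniformly among the forward pairs. The output
#' space matches the inference model: no self-loops, no mutual
#' regulation.
#'
#' @param n_genes number of genes.
#' @param n_edges number of directed edges (at most `choose(n_genes, 2)`).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return A [gene_network] with genes `G1..Gn`.
#' @examples
#' sim_network(10, 15, seed = 1)
#' @export
sim_network <- function(n_genes, n_edges, seed = NULL) {
  if (n_genes < 2L) stop("need at least 2 genes")
  maxe <- n_genes * (n_genes - 1L) / 2
  if (n_edges > maxe)
    stop("requested ", n_edges, " edges but at most ", maxe,
         " fit in an acyclic, non-mutual network on ", n_genes, " genes")
  genes <- paste0("G", seq_len(n_genes))
  with_seed(seed, {
    topo <- sample(genes)
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    pick <- if (n_edges > 0) sample(nrow(pairs), n_edges) else integer(0)
    gene_network(data.frame(regulator = topo[pairs[pick, 1L]],
                            target = topo[pairs[pick, 2L]],
                            stringsAsFactors = FALSE),
                 genes = genes)
  })
}

#' Simulate lagged regulatory time-series expression
#'
#' Discrete-time kinetics with saturating, normalized regulation and a
#' fixed regulatory delay. Each gene's production is bounded: with
#' regulators \eqn{r_1..r_m} of gene g,
#' \deqn{x_g(t+1) = d\,x_g(t) + b + \frac{s}{m}\sum_{i}
#'   u_i(x_{r_i}(t+1-\mathrm{lag})) + \epsilon_t}
#' where \eqn{u_i = \sigma} for an activating edge and
#' \eqn{u_i = 1 - \sigma} for a repressing one,
#' \eqn{\sigma(v) = 1/(1+e^{-(v - c)/w})}, and
#' \eqn{\epsilon_t \sim N(0, \mathrm{noise\_sd}^2)}. Production therefore
#' stays in `[b, b + s]` regardless of in-degree (saturating kinetics in
#' the spirit of normalized Hill regulation, so hub targets do not rail
#' against the clip bounds); unregulated genes produce at the mid level
#' `b + s/2` so all genes share the same typical scale. Values are
#' clipped to `[0, clip]`.
#'
#' Each series is an independent perturbation experiment: a random
#' subset of genes (each included with probability `perturb_prob`, at
#' least one per series) starts displaced to a random level spanning the
#' reachable range, while the remaining genes start at the mid steady
#' state; the relaxation from that state carries much of the
#' between-gene signal, as in multi-perturbation benchmark data.
#' Perturbing only a subset keeps unrelated genes from sharing a global
#' relaxation time course, which would otherwise make all pairs look
#' associated. Each edge's sign is drawn once with probability
#' `activation_prob` of activation.
#'
#' @param network a [gene_network] giving the ground truth.
#' @param n_series number of independent series (default 5).
#' @param n_points time points per series (default 21).
#' @param lag regulatory delay in sampling intervals (default 1).
#' @param strength regulation strength `s` (default 1).
#' @param noise_sd process noise standard deviation (default 0.05).
#' @param decay autoregressive retention `d` in (0,1) (default 0.5).
#' @param basal basal production `b` (default 0.5).
#' @param activation_prob probability an edge activates rather than
#'   represses (default 0.75).
#' @param sig_center,sig_width sigmoid center `c` and width `w`. The
#'   center defaults to the mid steady-state level
#'   `(b + s/2) / (1 - d)` (2 under the default rates, with levels
#'   spanning `[1, 3]`), so regulation is responsive around the
#'   operating point; width defaults to 0.4.
#' @param perturb_prob probability that a gene is perturbed in a given
#'   series (default 1/3, the typical fraction in benchmark
#'   perturbation designs); at least one gene is always perturbed.
#' @param clip upper clip bound; values are kept in `[0, clip]`
#'   (default 4).
#' @param seed optional integer seed.
#' @return An [expression_dataset]; the drawn edge signs are kept in its
#'   `signs` attribute.
#' @examples
#' net <- sim_network(10, 15, seed = 1)
#' ds <- sim_expression(net, seed = 1)
#' ds
#' @export
sim_expression <- function(network, n_series = 5, n_points = 21, lag = 1,
                           strength = 1, noise_sd = 0.05, decay = 0.5,
                           basal = 0.5, activation_prob = 0.75,
                           sig_center = NULL, sig_width = 0.4,
                           perturb_prob = 1 / 3, clip = 4, seed = NULL) {
  genes <- network$genes
  ng <- length(genes)
  ed <- network$edges
  if (lag < 1L || lag >= n_points) stop("'lag' must be in [1, n_points)")
  steady <- (basal + strength * 0.5) / (1 - decay)
  if (is.null(sig_center)) sig_center <- steady
  lo <- max(basal / (1 - decay) - 0.5, 0)       # perturbation range spans
  hi <- (basal + strength) / (1 - decay) + 0.5  # the reachable levels
  sig <- function(v) 1 / (1 + exp(-(v - sig_center) / sig_width))
  with_seed(seed, {
    signs <- if (nrow(ed))
      ifelse(stats::runif(nrow(ed)) < activation_prob, 1, -1)
    else numeric(0)
    reg_idx <- match(ed$regulator, genes)
    tgt_idx <- match(ed$target, genes)
    indeg <- tabulate(tgt_idx, ng)
    series <- vector("list", n_series)
    for (s in seq_len(n_series)) {
      m <- matrix(0, n_points, ng, dimnames = list(NULL, genes))
      mask <- stats::runif(ng) < perturb_prob
      if (!any(mask)) mask[sample.int(ng, 1L)] <- TRUE
      m[1L, mask] <- stats::runif(sum(mask), lo, hi)
      m[1L, !mask] <- steady + stats::rnorm(sum(!mask), 0, noise_sd)
      for (t in seq_len(n_points - 1L)) {
        reg_u <- rep(0.5, ng)  # unregulated genes: mid-level production
        tr <- t + 1L - lag  # regulator time index feeding t+1
        if (tr >= 1L && length(reg_idx)) {
          act <- sig(m[tr, reg_idx])
          u <- ifelse(signs > 0, act, 1 - act)
          tot <- rep(0, ng)
          for (e in seq_along(tgt_idx))
            tot[tgt_idx[e]] <- tot[tgt_idx[e]] + u[e]
          reg <- indeg > 0L
          reg_u[reg] <- tot[reg] / indeg[reg]
        }
        nxt <- decay * m[t, ] + basal + strength * reg_u +
          stats::rnorm(ng, 0, noise_sd)
        m[t + 1L, ] <- pmin(pmax(nxt, 0), clip)
      }
      series[[s]] <- m
    }
    ds <- expression_dataset(series, genes = genes,
                             times = lapply(series, function(x)
                               50 * (seq_len(nrow(x)) - 1)))
    attr(ds, "signs") <- signs
    ds
  })
}
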