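test_that("Z-score discretization follows the absolute-deviation rule", {
  # outlier detection with a pooled mean/sd
  d <- discretize_zscore(cbind(G1 = c(0, 0, 0, 10)), k = 1.2)
  expect_equal(unname(d[, 1]), c(0L, 0L, 0L, 1L))
  # both tails count: |x - mu| / sigma
  x <- c(-1.5, 0, 0, 0, 0, 1.5)
  sig <- sd(x) * sqrt(5 / 6)  # population divisor
  d2 <- discretize_zscore(cbind(G = x), k = 1.2)
  expect_equal(unname(d2[, 1]), as.integer(abs(x - mean(x)) / sig >= 1.2))
  expect_equal(unname(d2[1, 1]), 1L)  # negative excursion maps to 1 too
  # divisor switch moves boundary points only
  d3 <- discretize_zscore(cbind(G = x), k = 1.2, sd_divisor = "n-1")
  expect_equal(unname(d3[, 1]), as.integer(abs(x - mean(x)) / sd(x) >= 1.2))
  # constant gene: all zeros with a warning
  expect_warning(d4 <- discretize_zscore(cbind(G = rep(3, 5))), "constant")
  expect_equal(unname(d4[, 1]), rep(0L, 5))
  # series structure is preserved
  ds <- sim_expression(sim_network(3, 2, seed = 1), seed = 1)
  disc <- discretize_zscore(ds)
  expect_equal(attr(disc, "series"), rep(1:5, each = 21))
})

test_that("a perfect lagged copy orients from source to target", {
  set.seed(12)
  src <- sample(0:1, 40, replace = TRUE)
  tgt <- c(0L, src[-40])
  disc <- cbind(X = src, Y = tgt)
  rec <- orient_edge("X", "Y", disc)
  expect_equal(rec$regulator, "X")
  expect_equal(rec$target, "Y")
  expect_gt(rec$it_ab, rec$it_ba)
})

test_that("perfectly symmetric data falls back deterministically", {
  d <- cbind(B = c(0L, 1L, 0L, 1L, 1L, 0L), A = c(0L, 1L, 0L, 1L, 1L, 0L))
  rec <- orient_edge("B", "A", d)
  expect_equal(rec$rule, "unresolved")
  expect_equal(rec$regulator, "A")  # lexicographic fallback
  expect_equal(rec$sum_ab, rec$sum_ba)
})

test_that("the decision rule is argmax of CRAE + lagged MI with IT tiebreak", {
  set.seed(13)
  for (s in 1:25) {
    ds <- lagged_pair(seed = s)
    rec <- orient_edge("G1", "G2", discretize_zscore(ds))
    want <- if (rec$sum_ab > rec$sum_ba) "G1"
            else if (rec$sum_ab < rec$sum_ba) "G2"
            else if (rec$it_ab > rec$it_ba) "G1"
            else if (rec$it_ab < rec$it_ba) "G2"
            else "G1"
    expect_equal(rec$regulator, want)
    expect_equal(rec$crae_ab + rec$it_ab, rec$sum_ab)
  }
})

test_that("orientation conserves edges and never emits mutual pairs", {
  truth <- sim_network(10, 15, seed = 5)
  ds <- sim_expression(truth, seed = 5)
  scores <- suppressWarnings(mic_matrix(ds))
  skel <- prune_skeleton(build_skeleton(scores, 0.43), ds)
  net <- orient_edges(skel, discretize_zscore(ds))
  expect_equal(nrow(net$edges), nrow(skel$edges))
  expect_true(all(net$edges$regulator != net$edges$target))
  k <- paste(net$edges$regulator, net$edges$target)
  rk <- paste(net$edges$target, net$edges$regulator)
  expect_length(intersect(k, rk), 0)
  # empty skeleton gives an empty network
  empty <- build_skeleton(scores, 1.1)
  expect_equal(nrow(orient_edges(empty, discretize_zscore(ds))$edges), 0)
})

test_that("strongly lagged regulation is recovered well above chance", {
  correct <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    ds <- lagged_pair(seed = s, strength = 1.5, noise_sd = 0.02)
    rec <- orient_edge("G1", "G2", discretize_zscore(ds))
    if (rec$regulator == "G1") correct <- correct + 1
  }
  expect_lt(binom.test(correct, n_rep, 0.5, "greater")$p.value, 0.01)
  expect_gt(correct / n_rep, 0.5)
})

test_that("same input and config give byte-identical networks", {
  truth <- sim_network(6, 8, seed = 9)
  ds <- sim_expression(truth, seed = 9)
  run <- function() {
    scores <- suppressWarnings(mic_matrix(ds))
    skel <- prune_skeleton(build_skeleton(scores, 0.43), ds)
    net <- orient_edges(skel, discretize_zscore(ds))
    f <- tempfile(); write_network(net, f)
    on.exit(unlink(f))
    readBin(f, "raw", file.size(f))
  }
  expect_identical(run(), run())
})
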