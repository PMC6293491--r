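toy_scores <- function() {
  g <- c("A", "B", "C")
  s <- matrix(NA_real_, 3, 3, dimnames = list(g, g))
  s["A", "B"] <- s["B", "A"] <- 0.9
  s["A", "C"] <- s["C", "A"] <- 0.5
  s["B", "C"] <- s["C", "B"] <- 0.2
  s
}

test_that("thresholding keeps exactly the pairs scoring >= theta", {
  s <- toy_scores()
  sk <- build_skeleton(s, 0.43)
  expect_equal(nrow(sk$edges), 2)
  expect_setequal(paste(sk$edges$gene_a, sk$edges$gene_b),
                  c("A B", "A C"))
  expect_equal(nrow(build_skeleton(s, 0)$edges), 3)       # complete graph
  expect_equal(nrow(build_skeleton(s, 1 + 1e-9)$edges), 0) # empty graph
  # monotone in theta
  thetas <- seq(0, 1, by = 0.1)
  sizes <- vapply(thetas, function(th) nrow(build_skeleton(s, th)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ranked pair list is complete, sorted, and tie-stable", {
  set.seed(2)
  m <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("G", 1:5)))
  r <- rank_pairs(suppressWarnings(mic_matrix(m)))
  expect_equal(nrow(r), choose(5, 2))
  expect_true(all(diff(r$score) <= 0))
  # ties broken lexicographically: build a table with equal scores
  g <- c("A", "B", "C")
  s <- matrix(0.5, 3, 3, dimnames = list(g, g)); diag(s) <- NA
  r2 <- rank_pairs(s)
  expect_equal(paste(r2$gene_a, r2$gene_b), c("A B", "A C", "B C"))
})

test_that("triangle pruning removes the indirect chain edge", {
  removed_xz <- kept_true <- eligible <- 0
  for (s in 1:40) {
    M <- static_chain(seed = s)
    scores <- suppressWarnings(mic_matrix(M))
    if (min(scores, na.rm = TRUE) < 0.43) next
    eligible <- eligible + 1
    pruned <- prune_skeleton(build_skeleton(scores, 0.43), M)
    d <- attr(pruned, "pruned")
    keys <- paste(pruned$edges$gene_a, pruned$edges$gene_b)
    if (nrow(d) == 1 && d$gene_a == "G1" && d$gene_b == "G3")
      removed_xz <- removed_xz + 1
    if (all(c("G1 G2", "G2 G3") %in% keys)) kept_true <- kept_true + 1
  }
  expect_gt(eligible, 20)
  expect_gt(removed_xz / eligible, 0.5)   # indirect edge goes, usually
  expect_gt(kept_true / eligible, 0.5)    # direct edges stay, usually
})

test_that("pruning is a contraction and only ever touches triangles", {
  # no triangles: output identical to input
  g <- c("A", "B", "C", "D")
  s <- matrix(NA_real_, 4, 4, dimnames = list(g, g))
  s[lower.tri(s)] <- 0; s[upper.tri(s)] <- 0
  s["A", "B"] <- s["B", "A"] <- 0.9
  s["C", "D"] <- s["D", "C"] <- 0.9
  sk <- build_skeleton(s, 0.43)
  set.seed(1)
  M <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, g))
  pruned <- prune_skeleton(sk, M)
  expect_equal(pruned$edges, sk$edges)
  expect_equal(nrow(attr(pruned, "pruned")), 0)
  # contraction on arbitrary simulated systems
  for (s2 in 1:5) {
    truth <- sim_network(8, 12, seed = s2)
    ds <- sim_expression(truth, seed = s2)
    scores <- suppressWarnings(mic_matrix(ds))
    sk2 <- build_skeleton(scores, 0.3)
    pr2 <- suppressWarnings(prune_skeleton(sk2, ds))
    expect_lte(nrow(pr2$edges), nrow(sk2$edges))
    expect_true(all(paste(pr2$edges$gene_a, pr2$edges$gene_b) %in%
                      paste(sk2$edges$gene_a, sk2$edges$gene_b)))
  }
})

test_that("independent drivers of a common effect do not form a triangle", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(105); y <- rnorm(105)
    z <- x + y + rnorm(105, 0, 0.2)
    M <- cbind(G1 = x, G2 = y, G3 = z)
    scores <- suppressWarnings(mic_matrix(M))
    if (scores["G1", "G2"] >= 0.43) hits <- hits + 1
  }
  expect_lt(hits, 10)  # the driver pair itself rarely crosses theta
})

test_that("phase one is deterministic end to end", {
  truth <- sim_network(6, 8, seed = 3)
  ds <- sim_expression(truth, seed = 3)
  run <- function() {
    scores <- suppressWarnings(mic_matrix(ds))
    prune_skeleton(build_skeleton(scores, 0.43), ds)
  }
  a <- run(); b <- run()
  expect_identical(a$edges, b$edges)
  expect_identical(attr(a, "pruned"), attr(b, "pruned"))
})
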