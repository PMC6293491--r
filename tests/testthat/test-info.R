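test_that("discrete entropies match hand-computed values", {
  expect_equal(entropy_discrete(c(1, 1, 1, 1)), 0)
  expect_equal(entropy_discrete(c(0, 1, 0, 1)), 1)
  expect_equal(entropy_discrete(c(0, 0, 0, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(entropy_discrete(c(0, 0, 0, 1)), 0.811278, tolerance = 1e-6)
  # base switch: nats = bits * log(2)
  expect_equal(entropy_discrete(c(0, 0, 0, 1), base = exp(1)),
               0.811278 * log(2), tolerance = 1e-6)
  expect_error(entropy_discrete(numeric(0)), "empty")
})

test_that("joint and conditional entropy follow the chain identities", {
  expect_equal(joint_entropy_discrete(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(joint_entropy_discrete(c(0, 0, 1, 1), c(0, 1, 0, 1)), 2)
  expect_equal(joint_entropy_discrete(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  expect_equal(cond_entropy_discrete(c(0, 0, 1, 1), c(0, 1, 0, 1)), 1)
  expect_equal(cond_entropy_discrete(c(1, 0, 1, 0), c(0, 1, 0, 1)), 0)
  expect_error(joint_entropy_discrete(1:3, 1:4), "length")

  # exhaustive 4-symbol toy profiles: identities hold exactly
  syms <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  for (i in seq_len(nrow(syms))) for (j in seq_len(nrow(syms))) {
    x <- as.integer(syms[i, ]); y <- as.integer(syms[j, ])
    hx <- entropy_discrete(x); hy <- entropy_discrete(y)
    hxy <- joint_entropy_discrete(x, y)
    expect_equal(mi_discrete(x, y), hx + hy - hxy)
    expect_equal(cond_entropy_discrete(y, x), hxy - hx, tolerance = 1e-12)
    expect_gte(mi_discrete(x, y), -1e-9)
    expect_equal(mi_discrete(x, y), mi_discrete(y, x))
  }
})

test_that("discrete MI matches the contingency-table definition", {
  expect_equal(mi_discrete(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mi_discrete(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(mi_discrete(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0.311278,
               tolerance = 1e-6)
})

test_that("gaussian entropy matches its closed form", {
  z <- as.numeric(scale(rnorm(50)))  # exactly unit sample variance
  expect_equal(entropy_gaussian(z), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-10)
  expect_equal(entropy_gaussian(2 * z),
               entropy_gaussian(z) + 0.5 * log(4), tolerance = 1e-10)
  # block-diagonal: two uncorrelated unit-variance profiles
  set.seed(4)
  a <- rnorm(400); b <- rnorm(400)
  b <- as.numeric(scale(residuals(lm(b ~ a))))  # enforce exact rho = 0
  a <- as.numeric(scale(a))
  expect_equal(entropy_gaussian(cbind(a, b)),
               2 * 0.5 * log(2 * pi * exp(1)), tolerance = 1e-10)
})

test_that("gaussian MI equals -0.5 log(1 - rho^2) and is symmetric", {
  set.seed(11)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  rho <- cor(x, y)
  expect_equal(mi_gaussian(x, y), -0.5 * log(1 - rho^2), tolerance = 1e-10)
  expect_equal(mi_gaussian(x, y), mi_gaussian(y, x))
  # exact zero correlation
  y0 <- as.numeric(residuals(lm(y ~ x)))
  expect_equal(mi_gaussian(x, y0), 0, tolerance = 1e-10)
  expect_warning(mi_gaussian(x, x), "singular")
})

test_that("gaussian MI converges to the population value at n = 10000", {
  set.seed(21)
  n <- 10000
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(mi_gaussian(x, y) - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("gaussian CMI detects conditional independence", {
  set.seed(31)
  n <- 10000
  # Markov chain X -> Z -> Y, linear
  x <- rnorm(n); z <- 0.8 * x + rnorm(n); y <- 0.7 * z + rnorm(n)
  expect_lt(cmi_gaussian(x, y, z), 0.01)
  # Z unrelated: CMI reduces to MI
  z2 <- rnorm(n)
  expect_lt(abs(cmi_gaussian(x, y, z2) - mi_gaussian(x, y)), 0.01)
  # mutually uncorrelated triple
  expect_lt(cmi_gaussian(rnorm(n), rnorm(n), rnorm(n)), 0.01)
  # symmetry in the first two arguments
  set.seed(32)
  a <- rnorm(50); b <- rnorm(50); c <- rnorm(50)
  expect_equal(cmi_gaussian(a, b, c), cmi_gaussian(b, a, c))
  # exact linear copy: Y = Z carries nothing beyond Z
  suppressWarnings(expect_lt(
    cmi_gaussian(as.numeric(scale(rnorm(50))), c, c), 1e-6))
})

test_that("CRAE matches its definition and handles degenerate targets", {
  # deterministic target
  expect_equal(crae(c(0, 1, 0, 1), c(1, 0, 1, 0)), 0)
  # independent uniform binary: H(Y|X) = H(Y) = 1, |Y| = 2
  expect_equal(crae(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.5)
  # hand-evaluated 2x2 contingency
  expect_equal(crae(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               0.5 / (entropy_discrete(c(0, 1, 1, 1)) * 2))
  expect_equal(crae(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.308155,
               tolerance = 1e-5)
  # constant target never attracts an edge: CRAE defined as 0
  expect_equal(crae(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0)
})

test_that("time-lagged MI is directional and respects series structure", {
  set.seed(41)
  src <- sample(0:1, 60, replace = TRUE)
  tgt <- c(0L, src[-60])  # exact lag-1 copy
  expect_equal(mi_lagged(src, tgt, tdelay = 1),
               entropy_discrete(src[-60]))
  # tdelay = 0 reduces to plain MI
  expect_equal(mi_lagged(src, tgt, tdelay = 0), mi_discrete(src, tgt))
  # directionality: reverse direction carries less information
  expect_gt(mi_lagged(src, tgt, tdelay = 1), mi_lagged(tgt, src, tdelay = 1))
  # long independent profiles: near zero (below a null-calibrated bound)
  set.seed(42)
  a <- sample(0:1, 2000, replace = TRUE)
  b <- sample(0:1, 2000, replace = TRUE)
  expect_lt(mi_lagged(a, b, tdelay = 1), 0.005)
  expect_error(mi_lagged(a, b, tdelay = 2000), "tdelay")
})

test_that("lagged MI never pairs samples across series boundaries", {
  set.seed(43)
  ser <- rep(1:5, each = 21)
  x <- sample(0:1, 105, replace = TRUE)
  y <- sample(0:1, 105, replace = TRUE)
  v1 <- mi_lagged(x, y, ser, tdelay = 2)
  # permute whole series blocks: pooled value unchanged
  perm <- c(3, 1, 5, 2, 4)
  idx <- unlist(lapply(perm, function(s) which(ser == s)))
  v2 <- mi_lagged(x[idx], y[idx], rep(1:5, each = 21), tdelay = 2)
  expect_equal(v1, v2)
  # and differs (generically) from ignoring the boundaries
  expect_false(isTRUE(all.equal(v1, mi_lagged(x, y, tdelay = 2))))
})
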