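# Brute-force oracle: a straight-line, loop-based transcription of the
# entropy-weighting and ideal-solution equations, kept independent of
# the package's vectorized implementation.
topsis_oracle <- function(x, directions) {
  n <- nrow(x); m <- ncol(x)
  p <- matrix(0, n, m)
  for (j in 1:m) for (i in 1:n) p[i, j] <- x[i, j] / sum(x[, j])
  e <- numeric(m)
  for (j in 1:m) {
    s <- 0
    for (i in 1:n) if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j])
    e[j] <- -s / log(n)
  }
  d <- 1 - e
  w <- d / sum(d)
  v <- matrix(0, n, m)
  for (j in 1:m) for (i in 1:n) v[i, j] <- w[j] * p[i, j]
  vpos <- numeric(m); vneg <- numeric(m)
  for (j in 1:m) {
    if (directions[j] == "benefit") {
      vpos[j] <- max(v[, j]); vneg[j] <- min(v[, j])
    } else {
      vpos[j] <- min(v[, j]); vneg[j] <- max(v[, j])
    }
  }
  dpos <- numeric(n); dneg <- numeric(n)
  for (i in 1:n) {
    dpos[i] <- sqrt(sum((v[i, ] - vpos)^2))
    dneg[i] <- sqrt(sum((v[i, ] - vneg)^2))
  }
  list(w = w, e = e, closeness = dneg / (dpos + dneg))
}

test_that("proportion normalization matches worked values and sums to one", {
  expect_equal(unname(proportion_normalize(cbind(c(1, 1, 1, 1)))[, 1]),
               rep(0.25, 4))
  expect_equal(unname(proportion_normalize(cbind(c(1, 3)))[, 1]),
               c(0.25, 0.75))
  set.seed(501)
  x <- matrix(runif(40, 1, 9), 8, 5)
  expect_true(all(abs(colSums(proportion_normalize(x)) - 1) < 1e-12))
  expect_error(proportion_normalize(cbind(c(1, -2))), "positive")
  expect_error(proportion_normalize(cbind(c(0, 2))), "positive")
  expect_error(proportion_normalize(matrix(1, 1, 2)), "2 alternatives")
})

test_that("entropy extremes: uniform columns get zero weight, one-hot columns full dispersion", {
  p <- cbind(u = c(0.25, 0.25, 0.25, 0.25), h = c(1, 0, 0, 0),
             v = c(0.4, 0.3, 0.2, 0.1))
  ew <- entropy_weights(p)
  expect_equal(unname(ew$e[["u"]]), 1)
  expect_equal(unname(ew$d[["u"]]), 0)
  expect_equal(unname(ew$e[["h"]]), 0)   # exercises 0*ln0 = 0
  expect_equal(unname(ew$d[["h"]]), 1)
  expect_equal(sum(ew$w), 1, tolerance = 1e-12)
  expect_equal(unname(ew$w), unname(ew$d / sum(ew$d)))
  expect_error(entropy_weights(cbind(c(.5, .5), c(.5, .5))),
               "degenerate")
})

test_that("closeness equals the brute-force oracle on random positive matrices", {
  sch <- trait_schema()
  for (s in 1:20) {
    x <- generate_decision_fixture(5, sch, seed = 500 + s)
    res <- topsis_rank(x, sch)
    orc <- topsis_oracle(x, sch$direction)
    expect_equal(unname(res$closeness), orc$closeness, tolerance = 1e-12)
    expect_equal(unname(res$weights$w), orc$w, tolerance = 1e-12)
    expect_equal(sum(res$weights$w), 1, tolerance = 1e-12)
  }
})

test_that("dominant and anti-dominant alternatives pin the closeness scale", {
  sch <- trait_schema()
  xd <- generate_decision_fixture(5, sch, dominant = "A", seed = 9)
  expect_equal(unname(topsis_rank(xd, sch)$rank[["A"]]), 1)
  # two alternatives: the dominant one coincides with the ideal point
  x2 <- generate_decision_fixture(2, sch, dominant = "A", seed = 10)
  r2 <- topsis_rank(x2, sch)
  expect_equal(unname(r2$closeness[["A"]]), 1)
  expect_equal(unname(r2$closeness[["B"]]), 0)
})

test_that("identical rows give undefined closeness", {
  x <- matrix(5, 3, 15, dimnames = list(c("a", "b", "c"),
                                        trait_schema()$indicator))
  expect_error(topsis_rank(x), "degenerate|identical")
})

test_that("column rescaling leaves the full TOPSIS pipeline invariant", {
  sch <- trait_schema()
  x <- generate_decision_fixture(5, sch, seed = 12)
  base <- topsis_rank(x, sch)
  x2 <- x
  x2[, 3] <- x2[, 3] * 1000
  x2[, 8] <- x2[, 8] * 1e-4
  scaled <- topsis_rank(x2, sch)
  expect_equal(scaled$closeness, base$closeness, tolerance = 1e-12)
  expect_equal(scaled$weights$w, base$weights$w, tolerance = 1e-12)
})

test_that("duplicating an indicator changes entropy weights but not fixed-weight closeness", {
  sch <- trait_schema(c("cp", "adf", "hay_yield"))
  x <- generate_decision_fixture(4, sch, seed = 13)
  base <- topsis_rank(x, sch)
  sch2 <- data.frame(indicator = c(sch$indicator, "cp2"),
                     direction = c(sch$direction, "benefit"),
                     unit = NA)
  class(sch2) <- c("trait_schema", "data.frame")
  x2 <- cbind(x, cp2 = x[, "cp"])
  dup <- topsis_rank(x2, sch2)
  # entropy weighting re-splits mass: closeness is NOT invariant
  expect_false(isTRUE(all.equal(unname(dup$closeness),
                                unname(base$closeness))))
  # with externally fixed weights the duplicate changes nothing material
  w <- c(0.5, 0.3, 0.2)
  fixed <- topsis_rank(x, sch, weights = w)
  fixed_scaled <- topsis_rank(x * 2, sch, weights = w)
  expect_equal(fixed$closeness, fixed_scaled$closeness, tolerance = 1e-12)
})

test_that("improving a benefit entry never lowers fixed-weight closeness", {
  sch <- trait_schema(c("cp", "hay_yield", "adf"))
  w <- c(0.4, 0.4, 0.2)
  set.seed(502)
  for (rep in 1:10) {
    x <- generate_decision_fixture(4, sch, seed = 600 + rep)
    before <- topsis_rank(x, sch, weights = w)$closeness[["B"]]
    x2 <- x
    x2["B", "cp"] <- x2["B", "cp"] * 1.3
    # renormalize the column shift: keep other rows' raw values fixed
    after <- topsis_rank(x2, sch, weights = w)$closeness[["B"]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("min-max rescaling admits signed input to the ranking", {
  sch <- trait_schema(c("cp", "hay_yield", "adf"))
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(letters[1:4], sch$indicator))
  expect_error(topsis_rank(x, sch), "positive")
  res <- topsis_rank(x, sch, rescale = TRUE)
  expect_true(all(res$closeness >= 0 & res$closeness <= 1))
})
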