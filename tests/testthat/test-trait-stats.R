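test_that("Lilliefors test is calibrated under normality and powered against skew", {
  set.seed(301)
  p_null <- replicate(100, lilliefors_ks(rnorm(50))$p.value)
  rate <- mean(p_null < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)          # nominal 0.05 within binomial noise
  p_exp <- replicate(40, lilliefors_ks(rexp(200))$p.value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(lilliefors_ks(rep(3, 10)), "constant")
  expect_error(lilliefors_ks(c(1, 2, 3)), "at least 4")
})

test_that("Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(60, 5, 2)
    expect_equal(lilliefors_ks(x, n_rep = 100)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("median-based Levene test handles degenerate, null and unequal-variance groups", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  res <- levene_median(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_error(levene_median(list(1:3)), "at least 2 groups")
  expect_error(levene_median(list(1:3, 5)), "at least 2 observations")

  set.seed(302)
  rej <- replicate(400, {
    levene_median(list(rnorm(20), rnorm(20), rnorm(20)))$p.value < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  pow <- replicate(50, {
    levene_median(list(rnorm(50, sd = 1), rnorm(50, sd = 5)))$p.value < 0.05
  })
  expect_gte(mean(pow), 0.95)
})

test_that("median-based Levene agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(303)
  y <- c(rnorm(15), rnorm(15, sd = 3), rnorm(15, sd = 0.5))
  g <- factor(rep(1:3, each = 15))
  ours <- levene_median(split(y, g))
  ref <- car::leveneTest(y, g, center = median)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("two-way ANOVA matches hand-computed balanced sums of squares", {
  # 2x2 with 2 replicates: SS computable from cell/marginal means
  d <- data.frame(genotype = rep(c("a", "b"), each = 4),
                  year = rep(c("y1", "y2"), each = 2, times = 2),
                  y = c(3, 5, 10, 12, 6, 4, 14, 18))
  out <- twoway_anova(d, "y")
  gm <- mean(d$y)
  mg <- tapply(d$y, d$genotype, mean)
  my <- tapply(d$y, d$year, mean)
  mc <- tapply(d$y, interaction(d$genotype, d$year), mean)
  ss_g <- 4 * sum((mg - gm)^2)
  ss_y <- 4 * sum((my - gm)^2)
  ss_cells <- 2 * sum((mc - gm)^2)
  ss_gy <- ss_cells - ss_g - ss_y
  ss_e <- sum((d$y - mc[interaction(d$genotype, d$year)])^2)
  expect_equal(out$SS, c(ss_g, ss_y, ss_gy, ss_e))
  expect_equal(out$partial_eta2[1:3],
               c(ss_g, ss_y, ss_gy) / (c(ss_g, ss_y, ss_gy) + ss_e))
  expect_equal(out$df, c(1, 1, 1, 4))
})

test_that("ANOVA decomposition, noiseless limit and balance contract hold", {
  g_eff <- matrix(c(0, 5, 10, 0, 0), 5, 1,
                  dimnames = list(paste0("G", 1:5), "y"))
  spec <- effect_spec(paste0("G", 1:5), paste0("Y", 1:3), 2,
                      baseline = c(y = 50), genotype_effects = g_eff,
                      residual_sd = 0)
  tab <- generate_trial(spec, seed = 1)
  out <- suppressWarnings(twoway_anova(tab, "y"))
  expect_equal(out$partial_eta2[out$term == "genotype"], 1)
  expect_lt(out$SS[out$term == "year"], 1e-18)

  noisy <- generate_trial(null_spec_1ind(), seed = 4)
  a <- twoway_anova(noisy, "y")
  expect_equal(sum(a$SS), sum((noisy$y - mean(noisy$y))^2))
  expect_true(all(a$partial_eta2[1:3] >= 0 & a$partial_eta2[1:3] <= 1))
  expect_equal(sum(a$df), nrow(noisy) - 1)
  expect_error(twoway_anova(noisy[-1, ], "y"), "unbalanced")
})

test_that("planted interaction is detected by the factorial ANOVA", {
  gy <- as.vector(outer(paste0("G", 1:5), paste0("Y", 1:3), paste,
                        sep = ":"))
  gy_eff <- matrix(0, 15, 1, dimnames = list(gy, "y"))
  gy_eff["G1:Y1", ] <- 3   # 3 residual SDs in one cell
  spec <- effect_spec(paste0("G", 1:5), paste0("Y", 1:3), 4,
                      baseline = c(y = 50), interaction_effects = gy_eff,
                      residual_sd = 1)
  hits <- vapply(1:20, function(s) {
    a <- twoway_anova(generate_trial(spec, seed = s), "y")
    a$p[a$term == "genotype:year"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("LSD threshold, separation and letter display behave", {
  set.seed(304)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)),
                  y = c(rnorm(10, 0, 0.01), rnorm(10, 0, 0.01),
                        rnorm(10, 10, 0.01)))
  res <- lsd_pairwise(d, "y", "g")
  # hand-check the threshold formula
  a <- anova(lm(y ~ g, d))
  expect_equal(res$lsd, qt(0.975, a[2, "Df"]) *
                 sqrt(2 * a[2, "Mean Sq"] / 10))
  ab <- with(res$pairs, significant[(a == "a" & b == "b") |
                                      (a == "b" & b == "a")])
  expect_false(ab)
  expect_identical(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] %in%
                 c(res$letters[["a"]], res$letters[["b"]]))
  # significance flags match the threshold rule
  with(res$pairs, expect_equal(significant, abs(diff) > lsd))
  expect_error(lsd_pairwise(d[-1, ], "y", "g"), "balanced")
})

test_that("protected LSD controls the experimentwise null error rate", {
  set.seed(305)
  any_sig <- replicate(400, {
    d <- null_groups()
    any(lsd_pairwise(d, "y", "g")$pairs$significant)
  })
  expect_gte(mean(any_sig), 0.02)
  expect_lte(mean(any_sig), 0.09)
})

test_that("cv and the two-sample t behave on worked cases and properties", {
  expect_equal(cv(c(1, 2, 3)), 0.5)
  expect_equal(cv(rep(4, 6)), 0)
  x <- c(2, 5, 9, 14)
  expect_equal(cv(3 * x), cv(x))
  expect_error(cv(c(-1, 1)), "mean is zero")

  a <- c(1, 2, 3, 4)
  expect_equal(two_sample_t(a, a)$statistic, 0)
  expect_equal(two_sample_t(a, a)$p.value, 1)
  b <- c(2, 4, 7, 8)
  expect_equal(two_sample_t(a, b)$statistic,
               -two_sample_t(b, a)$statistic)
  expect_error(two_sample_t(1, a), "at least 2")
  set.seed(306)
  pow <- replicate(60, two_sample_t(rnorm(30), rnorm(30, 2))$p.value < 0.05)
  expect_gte(mean(pow), 0.95)
})
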