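test_that("basis sets match hand d-separation on canonical graphs", {
  # saturated: every pair adjacent
  sat <- path_model(y ~ x, z ~ x + y)
  expect_length(basis_set(sat), 0)
  # chain x -> m -> y: one claim, (x, y) given m
  chain <- path_model(m ~ x, y ~ m)
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$response, "y")
  expect_equal(bs[[1]]$other, "x")
  expect_equal(bs[[1]]$conditioning, "m")
  # two exogenous parents of one child: one unconditional claim
  vee <- path_model(c ~ a + b)
  bs2 <- basis_set(vee)
  expect_length(bs2, 1)
  expect_setequal(c(bs2[[1]]$response, bs2[[1]]$other), c("a", "b"))
  expect_length(bs2[[1]]$conditioning, 0)
  expect_error(path_model(a ~ b, b ~ a), "cyclic")
})

test_that("basis set is invariant to variable declaration order", {
  m1 <- path_model(stem_diameter ~ gxy, adf ~ gxy,
                   plant_height ~ genotype,
                   hay_yield ~ stem_diameter + adf + plant_height,
                   total_hay_yield ~ plant_height)
  m2 <- path_model(total_hay_yield ~ plant_height,
                   hay_yield ~ plant_height + adf + stem_diameter,
                   plant_height ~ genotype,
                   adf ~ gxy, stem_diameter ~ gxy)
  key <- function(bs) sort(vapply(bs, function(cl)
    paste(cl$response, cl$other,
          paste(cl$conditioning, collapse = ","), sep = "|"), ""))
  expect_equal(key(basis_set(m1)), key(basis_set(m2)))
})

test_that("Fisher's C combines claim p-values correctly", {
  expect_equal(fishers_c(c(1, 1, 1)),
               list(C = 0, df = 6L, p.value = 1))
  fc <- fishers_c(c(0.5, 0.5, 0.5))
  expect_equal(fc$C, 4.158883, tolerance = 1e-6)
  expect_equal(fc$df, 6L)
  # additivity over independent claim sets
  a <- c(0.3, 0.8); b <- c(0.05, 0.6, 0.9)
  expect_equal(fishers_c(c(a, b))$C,
               fishers_c(a)$C + fishers_c(b)$C)
  expect_error(fishers_c(c(0.5, 1.2)), "0, 1")
  expect_warning(f0 <- fishers_c(c(0.5, 0)), "floored")
  expect_true(is.finite(f0$C))
  expect_error(fishers_c(c(0.5, 0), zero_p = "error"), "infinite")
  expect_warning(sat <- fishers_c(numeric(0)), "saturated")
  expect_equal(sat, list(C = 0, df = 0L, p.value = 1))
})

test_that("identity path and standardization recovery hold", {
  d <- data.frame(x = rnorm(50))
  d$y <- d$x
  fit <- suppressWarnings(sem_fit(path_model(y ~ x), d))
  expect_equal(unname(coef(fit)[["x->y"]]), 1)

  truth <- sem_ground_truth(
    data.frame(parent = "x", child = "y", coefficient = -0.52),
    n = 10000, seed = 21)
  fit2 <- sem_fit(as_path_model(truth), generate_sem_dataset(truth))
  expect_lt(abs(coef(fit2)[["x->y"]] - (-0.52)), 0.03)
})

test_that("standardized beta equals the z-scored regression coefficient", {
  set.seed(601)
  d <- data.frame(a = rnorm(300), b = rnorm(300))
  d$y <- 0.4 * d$a - 0.7 * d$b + rnorm(300, sd = 2)
  fit <- sem_fit(path_model(y ~ a + b), d)
  zfit <- lm(scale(y) ~ scale(a) + scale(b), d)
  expect_equal(unname(coef(fit)), unname(coef(zfit)[2:3]),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear parent", {
  d <- data.frame(x = rnorm(30))
  d$x2 <- 2 * d$x
  d$y <- d$x + rnorm(30)
  expect_error(sem_fit(path_model(y ~ x + x2), d), "collinear")
})

test_that("categorical parents enter as dummy blocks with partial-F edge p-values", {
  set.seed(602)
  d <- data.frame(genotype = factor(rep(letters[1:5], each = 12)))
  d$height <- as.integer(d$genotype) + rnorm(60)
  d$yield <- 0.5 * d$height + rnorm(60)
  fit <- sem_fit(path_model(height ~ genotype, yield ~ height), d)
  ge <- fit$edges[fit$edges$parent == "genotype", ]
  expect_true(is.na(ge$beta))
  expect_lt(ge$p, 1e-6)
  ref <- anova(lm(height ~ genotype, d))[1, "Pr(>F)"]
  expect_equal(ge$p, ref, tolerance = 1e-12)
})

test_that("effect decomposition sums path products", {
  mk_fit <- function(edges) {
    eqs <- lapply(unique(edges$child), function(v)
      as.formula(paste(v, "~", paste(edges$parent[edges$child == v],
                                     collapse = "+"))))
    structure(list(model = path_model(eqs), edges = edges),
              class = "sem_fit")
  }
  chain <- mk_fit(data.frame(parent = c("x", "m"), child = c("m", "y"),
                             b = NA, beta = c(0.5, 0.4), p = NA))
  dec <- decompose_effects(chain, "x", "y")
  expect_equal(dec$direct, 0)
  expect_equal(dec$indirect, 0.2)
  expect_equal(dec$total, 0.2)

  direct <- mk_fit(data.frame(parent = "x", child = "y",
                              b = NA, beta = 0.3, p = NA))
  dd <- decompose_effects(direct, "x", "y")
  expect_equal(dd$total, dd$direct)
  expect_equal(dd$indirect, 0)

  par2 <- mk_fit(data.frame(
    parent = c("x", "x", "m1", "m2"), child = c("m1", "m2", "y", "y"),
    b = NA, beta = c(0.5, 0.5, 0.2, -0.2), p = NA))
  dp <- decompose_effects(par2, "x", "y")
  expect_equal(dp$indirect, 0, tolerance = 1e-15)
  expect_error(decompose_effects(par2, "x", "zz"), "not in model")
})

test_that("the reference yield DAG is recovered with mediated effects intact", {
  truth <- yield_path_truth(n = 10000, seed = 22)
  fit <- sem_fit(as_path_model(truth), generate_sem_dataset(truth))
  cf <- coef(fit)
  expect_lt(abs(cf[["gxy->stem_diameter"]] - (-0.52)), 0.03)
  expect_lt(abs(cf[["gxy->adf"]] - 0.70), 0.03)
  expect_lt(abs(cf[["plant_height->hay_yield"]] - 0.54), 0.03)
  dec <- decompose_effects(fit, "gxy", "hay_yield")
  # two mediated channels: via stem diameter and via ADF
  expect_equal(dec$indirect,
               cf[["gxy->stem_diameter"]] * cf[["stem_diameter->hay_yield"]] +
                 cf[["gxy->adf"]] * cf[["adf->hay_yield"]],
               tolerance = 1e-12)
  # data simulated from the declared DAG should fit acceptably
  expect_gt(fit$p.value, 0.01)
})
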