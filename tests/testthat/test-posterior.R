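# builds a factor-model posterior_draws object from an explicit
# draws x mutations x ages array of effects
fake_factor_draws <- function(effects, ages = c(5L, 19L, 33L),
                              chains = 2L) {
  stopifnot(length(dim(effects)) == 3L)
  ids <- dimnames(effects)[[2]] %||% sprintf("m%02d", seq_len(dim(effects)[2]))
  nd <- dim(effects)[1]
  stopifnot(nd %% chains == 0)
  pn <- as.vector(outer(ids, ages, function(m, a) sprintf("phi[%s,%d]", m, a)))
  arr <- array(NA_real_, c(chains, nd / chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  k <- 0L
  for (a in seq_along(ages)) for (m in seq_along(ids)) {
    k <- k + 1L
    arr[, , k] <- matrix(effects[, m, a], chains, nd / chains, byrow = TRUE)
  }
  posterior_draws(arr, parameterization = list(
    model = "aging", age_coding = "factor", mutation_ids = ids,
    assay_ages = as.integer(ages)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("p_mcmc counts tails as defined", {
  expect_equal(p_mcmc(c(1, 2, 3, -1)), 0.5)
  expect_equal(p_mcmc(c(0.3, 5, 2)), 0)
  expect_equal(p_mcmc(c(-3, -1, 1, 3)), 1)
  expect_error(p_mcmc(numeric(0)), "empty")
  expect_error(p_mcmc(c(1, NA)), "non-finite")
})

test_that("p_mcmc is invariant to positive scaling and to sign flip", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(500, mean = runif(1, -1, 1))
    p <- p_mcmc(x)
    expect_identical(p_mcmc(3.7 * x), p)
    expect_identical(p_mcmc(x^3), p)        # monotone, sign-preserving
    expect_identical(p_mcmc(-x), p)
  }
})

test_that("interval aging telescopes exactly and acceleration is its contrast", {
  set.seed(7)
  eff <- array(rnorm(400 * 3 * 3), c(400, 3, 3),
               dimnames = list(NULL, c("a", "b", "c"), NULL))
  pd <- fake_factor_draws(eff)
  for (m in c("a", "b", "c")) {
    d1 <- interval_aging(pd, m, c(5, 19))
    d2 <- interval_aging(pd, m, c(19, 33))
    d3 <- interval_aging(pd, m, c(5, 33))
    expect_equal(d1$estimate + d2$estimate, d3$estimate, tolerance = 1e-12)
    acc <- aging_acceleration(pd, m)
    expect_equal(acc$estimate, d2$estimate - d1$estimate, tolerance = 1e-12)
  }
  expect_error(interval_aging(pd, "a", c(5, 7)), "distinct assay ages")
  expect_error(interval_aging(pd, "zz", c(5, 19)), "lookup error")
})

test_that("deleteriousness maps log effects to the s scale", {
  arr <- array(0, c(2, 50, 2),
               dimnames = list(NULL, NULL, c("alpha[A]", "theta[A]")))
  pd <- posterior_draws(arr, parameterization = list(
    model = "deleteriousness", mutation_ids = "A"))
  z <- deleteriousness(pd, "A")
  expect_identical(z$estimate, 0)           # draws identically 0 -> s = 0
  arr[, , "theta[A]"] <- log(0.8)
  pd <- posterior_draws(arr, parameterization = list(
    model = "deleteriousness", mutation_ids = "A"))
  expect_equal(deleteriousness(pd, "A")$estimate, 0.2)
  expect_error(deleteriousness(pd, "B"), "lookup error")
})

test_that("estimand extractors enforce the model and age coding", {
  eff <- array(rnorm(100 * 2 * 3), c(100, 2, 3))
  pd <- fake_factor_draws(eff)
  expect_error(aging_coefficient(pd, "m01"), "coding error")
  expect_error(deleteriousness(pd, "m01"), "coding error")
})

test_that("among-line variance is translation invariant and zero for identical effects", {
  set.seed(9)
  base <- array(rnorm(200 * 4 * 3), c(200, 4, 3))
  pd <- fake_factor_draws(base)
  v <- among_line_variance(pd, 19)
  shifted <- base + array(rep(rnorm(200), 4 * 3), c(200, 4, 3))  # same shift all lines
  vs <- among_line_variance(fake_factor_draws(shifted), 19)
  expect_equal(v$estimate, vs$estimate, tolerance = 1e-12)

  same <- array(rep(rnorm(200 * 3), each = 1), c(200, 1, 3))
  same <- array(same[, rep(1, 4), ], c(200, 4, 3))
  pd0 <- fake_factor_draws(same)
  expect_equal(among_line_variance(pd0, 5)$estimate, 0)
  z <- variance_increase(pd0, c(5, 33))
  expect_equal(z$estimate, 0)
  expect_error(among_line_variance(pd, 19, "m01"), ">= 2 mutations")
})

test_that("variance_increase detects fanning effects in the draws", {
  set.seed(11)
  spread <- c(0.1, 0.5, 1.5)  # SD of effects grows with age
  eff <- array(NA_real_, c(300, 6, 3))
  centers <- seq(-1, 1, length.out = 6)
  for (a in 1:3) eff[, , a] <- matrix(rep(centers * spread[a], each = 300), 300, 6) +
      rnorm(300 * 6, 0, 0.05)
  pd <- fake_factor_draws(eff)
  z <- variance_increase(pd, c(5, 33))
  expect_gt(z$estimate, 0)
  expect_lt(z$p_mcmc, 0.01)
})
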