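test_that("draw bookkeeping: chains x (iterations - warmup) kept draws", {
  ds <- cached("ds_small", simulate_experiment(sim_config(
    n_mutations = 2, vials_per_mutation = 6, delta = c(0, log(0.8)),
    beta = c(0, -0.02), seed = 31)))
  fit <- cached("fit_small_pois", suppressWarnings(fit_deleteriousness_model(
    ds, "first", spec = fast_spec("poisson-log"), seed = 5)))
  expect_equal(dim(fit$draws)[1:2], c(2L, 600L))
  expect_true(all(c("theta[m01]", "theta[m02]", "sigma_vial") %in%
                  parameter_names(fit)))
  expect_true(all(is.finite(fit$draws)))
  expect_error(draws_of(fit, "nope"), "lookup error")
})

test_that("symmetric counts give a type effect centred on zero", {
  obs <- do.call(rbind, lapply(1:8, function(v) {
    data.frame(mutation = "A", vial = as.character(v), age_day = 5L,
               class = c("mut", "wt"), n_females = 25L, eggs = c(100L, 100L))
  }))
  ds <- fecundity_dataset(obs)
  fit <- suppressWarnings(fit_deleteriousness_model(
    ds, "first", spec = fast_spec("poisson-log"), seed = 6))
  expect_lt(abs(mean(draws_of(fit, "theta[A]"))), 0.05)
})

test_that("single-group Poisson posterior approaches the sample mean (conjugate limit)", {
  set.seed(40)
  y <- rpois(400, 120)
  obs <- do.call(rbind, lapply(seq(1, 400, by = 2), function(v) {
    data.frame(mutation = "A", vial = as.character(v), age_day = 5L,
               class = c("mut", "wt"), n_females = 25L,
               eggs = c(y[v], y[v + 1]), stringsAsFactors = FALSE)
  }))
  ds <- fecundity_dataset(obs)
  fit <- suppressWarnings(fit_deleteriousness_model(
    ds, "first", spec = fast_spec("poisson-log"), seed = 7))
  # alpha is the log wildtype-cell mean; theta ~ 0; vial SD ~ 0
  lam <- mean(exp(draws_of(fit, "alpha[A]")))
  expect_equal(lam, mean(y), tolerance = 0.03 * mean(y))
})

test_that("day-5 Poisson effect recovers generator truth with sigma_vial = 0", {
  ds <- simulate_experiment(sim_config(
    n_mutations = 1, vials_per_mutation = 200, vial_sd = 0,
    assay_ages = 5L, age_effects = 0, delta = log(0.8), seed = 44))
  fit <- suppressWarnings(fit_deleteriousness_model(
    ds, "first", spec = fast_spec("poisson-log"), seed = 8))
  th <- draws_of(fit, "theta[m01]")
  ci <- quantile(th, c(0.025, 0.975))
  expect_gt(log(0.8), ci[1]); expect_lt(log(0.8), ci[2])
  z <- deleteriousness(fit, "m01")
  expect_equal(z$estimate, 0.2, tolerance = 0.05)
})

test_that("binomial conditioning equals the log rate ratio of paired Poissons", {
  # generator property feeding the aging model: mut | total ~ Binomial with
  # logit p = log(lam_mut / lam_wt), independent of the shared vial mean
  ds <- simulate_experiment(sim_config(
    n_mutations = 1, vials_per_mutation = 3000, vial_sd = 0.3,
    assay_ages = 5L, age_effects = 0, delta = log(0.6), seed = 45))
  pc <- paired_counts(ds)
  phat <- sum(pc$mut_eggs) / sum(pc$mut_eggs + pc$wt_eggs)
  expect_equal(qlogis(phat), log(0.6), tolerance = 0.02)
})

test_that("covariate and factor codings agree: effect(33) - effect(5) ~ slope x 28", {
  ds <- cached("ds_aging", simulate_experiment(sim_config(
    n_mutations = 2, vials_per_mutation = 20, delta = c(-0.1, -0.4),
    beta = c(-0.01, -0.025), seed = 46)))
  cov_fit <- cached("fit_aging_cov", suppressWarnings(fit_aging_model(
    ds, "covariate", spec = fast_spec("binomial-logit", "covariate"), seed = 9)))
  fac_fit <- cached("fit_aging_fac", suppressWarnings(fit_aging_model(
    ds, "factor", spec = fast_spec("binomial-logit", "factor"), seed = 10)))
  for (m in c("m01", "m02")) {
    slope <- aging_coefficient(cov_fit, m)$estimate
    span <- interval_aging(fac_fit, m, c(5, 33))$estimate
    expect_equal(span, slope * 28, tolerance = 0.15 + 0.1 * abs(span))
  }
})

test_that("aging fits drop zero-total vial-ages and need two ages", {
  obs <- rbind(
    toy_obs(0L, 0L, vial = "1", age_day = 5L),
    toy_obs(40L, 50L, vial = "1", age_day = 19L),
    toy_obs(30L, 40L, vial = "2", age_day = 5L),
    toy_obs(20L, 30L, vial = "2", age_day = 19L))
  ds <- fecundity_dataset(obs)
  expect_message(
    fit_aging_model(ds, "covariate",
                    spec = fast_spec("binomial-logit", "covariate"),
                    seed = 11, quiet = TRUE),
    "zero total eggs")
  ds5 <- fecundity_dataset(obs[obs$age_day == 5L, ])
  expect_error(fit_aging_model(ds5, "covariate"), "design error")
})

test_that("ML cross-check: JAGS day-5 effects track glmer estimates", {
  skip_if_not_installed("lme4")
  ds <- cached("ds_small", simulate_experiment(sim_config(
    n_mutations = 2, vials_per_mutation = 6, delta = c(0, log(0.8)),
    beta = c(0, -0.02), seed = 31)))
  fit <- cached("fit_small_pois", suppressWarnings(fit_deleteriousness_model(
    ds, "first", spec = fast_spec("poisson-log"), seed = 5)))
  obs <- ds$observations[ds$observations$age_day == 5L, ]
  obs$is_mut <- as.integer(obs$class == "mut")
  obs$vid <- paste(obs$mutation, obs$vial)
  gm <- lme4::glmer(eggs ~ 0 + mutation + mutation:is_mut + (1 | vid),
                    data = obs, family = poisson)
  ml <- lme4::fixef(gm)
  for (m in c("m01", "m02")) {
    bayes <- mean(draws_of(fit, sprintf("theta[%s]", m)))
    freq <- ml[[sprintf("mutation%s:is_mut", m)]]
    expect_equal(bayes, freq, tolerance = 0.05 + 0.1 * abs(freq))
  }
})

test_that("split R-hat is ~1 for stationary chains and large for shifted chains", {
  set.seed(50)
  good <- array(rnorm(4 * 1000 * 2), c(4, 1000, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  rh <- gelman_rubin(good)
  expect_true(all(rh < 1.02))

  bad <- good
  bad[1, , 1] <- bad[1, , 1] + 10   # one chain at a different constant
  expect_gt(gelman_rubin(bad)[["a"]], 2)

  # within-chain drift is caught by the split
  drift <- good
  drift[, , 2] <- drift[, , 2] + outer(rep(1, 4), seq(0, 5, length.out = 1000))
  expect_gt(gelman_rubin(drift)[["b"]], 1.3)

  expect_error(gelman_rubin(good[1, , , drop = FALSE]), "at least 2 chains")
})

test_that("split R-hat agrees with coda's PSRF on stationary chains", {
  set.seed(51)
  arr <- array(rnorm(2 * 2000 * 3), c(2, 2000, 3),
               dimnames = list(NULL, NULL, c("a", "b", "c")))
  mine <- gelman_rubin(arr)
  ml <- coda::mcmc.list(lapply(1:2, function(k) coda::mcmc(arr[k, , ])))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1]
  # split vs unsplit versions coincide for stationary chains up to MC noise
  expect_equal(unname(mine), unname(ref), tolerance = 0.01)
})

test_that("model_spec enforces its invariants", {
  expect_error(model_spec("poisson-log", chains = 1), "chains")
  expect_error(model_spec("poisson-log", iterations = 100, warmup = 100),
               "warmup")
})
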