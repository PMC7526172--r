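test_that("a minimal paired file loads and an unpaired one errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy_obs(), path, row.names = FALSE)
  ds <- load_fecundity_table(path)
  expect_s3_class(ds, "fecundity_dataset")
  expect_equal(nrow(ds$observations), 2L)
  expect_equal(ds$assay_ages, 5L)

  write.csv(toy_obs()[1, ], path, row.names = FALSE)  # drop the wildtype row
  expect_error(load_fecundity_table(path), "pairing error.*vial 1.*day 5")
})

test_that("schema mapping renames columns and names missing ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  renamed <- toy_obs()
  names(renamed)[names(renamed) == "eggs"] <- "egg_count"
  write.csv(renamed, path, row.names = FALSE)
  expect_error(load_fecundity_table(path), "schema error.*eggs")
  ds <- load_fecundity_table(path, schema = c(eggs = "egg_count"))
  expect_equal(ds$observations$eggs, c(50L, 60L))
})

test_that("validation rejects bad values and mismatched pairs", {
  expect_error(fecundity_dataset(toy_obs(mut_eggs = -1L)), "non-negative")
  expect_error(fecundity_dataset(toy_obs(n_females = 0L)), "positive")
  bad <- toy_obs()
  bad$n_females <- c(25L, 20L)
  expect_error(fecundity_dataset(bad), "unequal n_females")
  dup <- rbind(toy_obs(), toy_obs())
  expect_error(fecundity_dataset(dup), "pairing error")
})

test_that("write -> load round-trips a simulated dataset field by field", {
  ds <- simulate_experiment(sim_config(
    n_mutations = 3, vials_per_mutation = c(4, 6), seed = 11,
    delta = c(0, -0.2, -0.5), beta = c(0, 0, -0.02),
    survival = list(wt_logit = 2, coupling = 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_fecundity_table(ds, path, survival_path = spath)
  ds2 <- load_fecundity_table(path, survival_path = spath)
  expect_equal(ds2$observations, ds$observations)
  expect_equal(ds2$survival, ds$survival)
  expect_equal(ds2$assay_ages, ds$assay_ages)
  expect_equal(ds2$mutation_ids, ds$mutation_ids)
})

test_that("relative_fecundity applies the +1 offset and is antisymmetric", {
  expect_identical(relative_fecundity(0, 0), 0)
  expect_identical(relative_fecundity(99, 99), 0)
  expect_equal(relative_fecundity(49, 99), log(0.5))
  for (i in 1:50) {
    a <- rpois(1, 30); b <- rpois(1, 30)
    expect_equal(relative_fecundity(a, b), -relative_fecundity(b, a))
  }
  expect_error(relative_fecundity(-1, 5), "non-negative")
})

test_that("median relative fecundity matches hand computation and ignores vial order", {
  # per-vial log ratios exp-constructed so medians are exact
  mk <- function(r) as.integer(round(exp(r) * 100 - 1))
  ds <- toy_dataset(mut_eggs = mk(c(-0.2, 0, -0.5)), wt_eggs = c(99L, 99L, 99L))
  expect_equal(median_relative_fecundity(ds, "A", 5), -0.2, tolerance = 0.02)

  ds_eq <- toy_dataset(mut_eggs = c(10L, 20L, 30L), wt_eggs = c(10L, 20L, 30L))
  expect_identical(median_relative_fecundity(ds_eq, "A", 5), 0)

  shuffled <- fecundity_dataset(ds$observations[sample(nrow(ds$observations)), ])
  expect_equal(median_relative_fecundity(shuffled, "A", 5),
               median_relative_fecundity(ds, "A", 5))

  expect_error(median_relative_fecundity(ds, "Z", 5), "lookup error")
  expect_error(median_relative_fecundity(ds, "A", 7), "lookup error")
})

test_that("simulated medians recover the generator's per-vial log ratio", {
  cfg <- sim_config(n_mutations = 1, vials_per_mutation = 22, vial_sd = 0.2,
                    assay_ages = 5L, age_effects = 0, delta = -0.3, seed = 5)
  meds <- vapply(1:20, function(s) {
    cfg$seed <- s
    median_relative_fecundity(simulate_experiment(cfg), "m01", 5)
  }, 0)
  # median over 22 vials of a ratio of Poisson(~100) counts; generous band
  expect_lt(abs(mean(meds) + 0.3), 0.05)
})
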