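# Orchestration: simulate (or take) a dataset, fit the model suite, derive
# the per-mutation report and the pleiotropy correlations, optionally write
# everything to disk. All randomness flows from one seed.

#' Run the full analysis pipeline
#'
#' Composes the analysis end to end: (optionally) simulate a dataset, fit
#' the four model runs (Poisson day-5, Poisson summed, binomial with age as
#' covariate, binomial with age as factor), build the [aging_report()], and
#' compute the pleiotropy correlation suite on the all-lines, deleterious
#' and aging subsets. Deterministic given `seed` (stage seeds are derived
#' from it).
#'
#' @param ds a [fecundity_dataset()]; if `NULL`, one is simulated from
#'   `config`.
#' @param config a [sim_config()] used when `ds` is `NULL` (default:
#'   [sim_config_study()] seeded from `seed`).
#' @param models subset of
#'   `c("day5", "summed", "covariate", "factor")` to fit; the report uses
#'   whatever is available.
#' @param chains,iterations,warmup MCMC settings applied to every fit.
#' @param alpha classification threshold.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, write `data.csv` (and `survival.csv`),
#'   `report.json`, `tau.json` and `run_log.txt` there.
#' @param quiet suppress sampler progress output.
#' @return An object of class `fecage_analysis`: list with `data`, `fits`,
#'   `report`, `pleiotropy`, `rhat_max`, `seed`, `settings`.
#' @export
run_full_analysis <- function(ds = NULL, config = NULL,
                              models = c("day5", "summed", "covariate", "factor"),
                              chains = 4L, iterations = 4000L, warmup = 1000L,
                              alpha = 0.05, seed = 1L, out_dir = NULL,
                              quiet = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  simulated <- is.null(ds)
  if (simulated) {
    if (is.null(config)) config <- sim_config_study(seed = seed)
    ds <- simulate_experiment(config)
  }
  mk_spec <- function(family, age_coding = NULL) {
    model_spec(family, age_coding = age_coding, chains = chains,
               iterations = iterations, warmup = warmup)
  }
  fits <- list(day5 = NULL, summed = NULL, covariate = NULL, factor = NULL)
  if ("day5" %in% models) {
    fits$day5 <- fit_deleteriousness_model(
      ds, "first", spec = mk_spec("poisson-log"), seed = seed + 101L, quiet = quiet)
  }
  if ("summed" %in% models) {
    fits$summed <- fit_deleteriousness_model(
      ds, "summed", spec = mk_spec("poisson-log"), seed = seed + 102L, quiet = quiet)
  }
  if ("covariate" %in% models) {
    fits$covariate <- fit_aging_model(
      ds, "covariate", spec = mk_spec("binomial-logit", "covariate"),
      seed = seed + 103L, quiet = quiet)
  }
  if ("factor" %in% models) {
    fits$factor <- fit_aging_model(
      ds, "factor", spec = mk_spec("binomial-logit", "factor"),
      seed = seed + 104L, quiet = quiet)
  }
  report <- aging_report(ds, fit_day5 = fits$day5, fit_summed = fits$summed,
                         fit_covariate = fits$covariate,
                         fit_factor = fits$factor, alpha = alpha)

  pleio <- .pleiotropy_suite(ds, report)

  rhat_max <- vapply(fits, function(f) {
    if (is.null(f)) NA_real_ else max(f$rhat, na.rm = TRUE)
  }, 0)

  out <- structure(
    list(data = ds, fits = fits, report = report, pleiotropy = pleio,
         rhat_max = rhat_max, seed = seed, simulated = simulated,
         settings = list(models = models, chains = chains,
                         iterations = iterations, warmup = warmup,
                         alpha = alpha)),
    class = "fecage_analysis")
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

# tau suite over the subsets the report defines
.pleiotropy_suite <- function(ds, report) {
  tab <- report$mutations
  ages <- ds$assay_ages
  subsets <- list(all = ds$mutation_ids,
                  deleterious = tab$mutation[tab$deleterious],
                  aging = tab$mutation[tab$aging])
  rows <- list()
  add <- function(subset_name, comparison, tr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subset = subset_name, comparison = comparison,
      tau = tr$tau, p = tr$p_two_tailed, n = tr$n, method = tr$method,
      stringsAsFactors = FALSE)
  }
  prs <- if (length(ages) >= 2L) utils::combn(ages, 2L, simplify = FALSE) else list()
  for (sn in names(subsets)) {
    sub <- subsets[[sn]]
    if (length(sub) < 3L) next
    for (pr in prs) {
      add(sn, sprintf("fec%d_vs_fec%d", pr[1L], pr[2L]),
          age_pleiotropy(ds, sub, pr))
      add(sn, sprintf("change%d_%d_vs_level%d", pr[1L], pr[2L], pr[1L]),
          aging_vs_deleteriousness(ds, sub, pr))
    }
    if (!is.null(ds$survival)) {
      add(sn, sprintf("fec%d_vs_surv%d", ages[1L], ages[length(ages)]),
          survival_pleiotropy(ds, sub))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.fecage_analysis <- function(x, ...) {
  cat("<fecage_analysis> seed", x$seed,
      if (x$simulated) "(simulated data)" else "(supplied data)", "\n")
  cat("  fits:", paste(names(Filter(Negate(is.null), x$fits)), collapse = ", "),
      "  max split R-hat:",
      round(max(x$rhat_max, na.rm = TRUE), 4), "\n\n")
  print(x$report)
  invisible(x)
}

.write_bundle <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fecundity_table(
    x$data, file.path(out_dir, "data.csv"),
    survival_path = if (!is.null(x$data$survival)) file.path(out_dir, "survival.csv"))
  report <- list(seed = x$seed, settings = x$settings,
                 alpha = x$report$alpha,
                 rhat_max = as.list(x$rhat_max),
                 mutations = x$report$mutations,
                 variance = x$report$variance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(x$pleiotropy, file.path(out_dir, "tau.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log_lines <- c(
    sprintf("seed: %d", x$seed),
    sprintf("models: %s", paste(x$settings$models, collapse = ", ")),
    sprintf("chains: %d  iterations: %d  warmup: %d",
            x$settings$chains, x$settings$iterations, x$settings$warmup),
    sprintf("alpha: %g", x$settings$alpha),
    sprintf("max split R-hat per fit: %s",
            paste(sprintf("%s=%.4f", names(x$rhat_max), x$rhat_max),
                  collapse = "  ")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(x)
}
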