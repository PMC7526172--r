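# Posterior-derived estimands and tests. Every estimand is a per-draw
# functional of the model coefficients, summarized by its posterior mean,
# central 95% credibility interval (2.5% and 97.5% quantiles, type-7) and
# p_mcmc, the two-tailed posterior probability analogue.

#' Two-tailed posterior probability (p_mcmc)
#'
#' Twice the smaller of the proportions of draws below and above zero,
#' capped at 1: `2 * min(mean(x < 0), mean(x > 0))`.
#'
#' @param x numeric vector of posterior draws of a scalar quantity.
#' @return scalar in \[0, 1\].
#' @export
p_mcmc <- function(x) {
  if (length(x) == 0L) stop("p_mcmc: empty draw vector", call. = FALSE)
  if (!all(is.finite(x))) stop("p_mcmc: non-finite draws", call. = FALSE)
  min(1, 2 * min(mean(x < 0), mean(x > 0)))
}

# Central 95% posterior interval (quantile type 7, R default).
.ci95 <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

.summarize_draws <- function(draws, p_draws = draws) {
  ci <- .ci95(draws)
  list(estimate = mean(draws), lower = ci[["lower"]], upper = ci[["upper"]],
       p_mcmc = p_mcmc(p_draws))
}

.check_model <- function(pd, model, age_coding = NULL) {
  stopifnot(inherits(pd, "posterior_draws"))
  pz <- pd$parameterization
  if (!identical(pz$model, model)) {
    stop("coding error: expected draws from the ", model, " model", call. = FALSE)
  }
  if (!is.null(age_coding) && !identical(pz$age_coding, age_coding)) {
    stop("coding error: expected age coded as ", age_coding,
         " (got ", pz$age_coding %||% "none", ")", call. = FALSE)
  }
  invisible(pz)
}

.check_mutation <- function(pd, mutation_id) {
  ids <- pd$parameterization$mutation_ids
  if (!mutation_id %in% ids) {
    stop("lookup error: unknown mutation: ", mutation_id, call. = FALSE)
  }
  mutation_id
}

#' Deleteriousness of a mutation, s = 1 - mut/wt
#'
#' Per draw, `s = 1 - exp(theta[m])` where `theta[m]` is the log
#' mutant/wildtype fecundity ratio from the Poisson model; positive values
#' indicate a deleterious effect. `p_mcmc` is computed on the log-scale
#' effect (which shares its sign with s up to reflection, so the tail
#' proportions are identical).
#'
#' @param pd draws from [fit_deleteriousness_model()].
#' @param mutation_id mutation label.
#' @return list with `estimate` (posterior mean of s), `lower`, `upper`
#'   (central 95% interval of s) and `p_mcmc`.
#' @export
deleteriousness <- function(pd, mutation_id) {
  .check_model(pd, "deleteriousness")
  .check_mutation(pd, mutation_id)
  th <- draws_of(pd, sprintf("theta[%s]", mutation_id))
  .summarize_draws(1 - exp(th), p_draws = th)
}

#' Per-day rate of reproductive aging of a mutation
#'
#' Posterior of the per-day slope of the log mutant/wildtype fecundity ratio
#' (logit scale of the binomial aging model with age as a covariate).
#' Negative values indicate faster aging for the mutant.
#'
#' @param pd draws from `fit_aging_model(ds, "covariate")`.
#' @param mutation_id mutation label.
#' @return list with `estimate`, `lower`, `upper`, `p_mcmc`.
#' @export
aging_coefficient <- function(pd, mutation_id) {
  .check_model(pd, "aging", age_coding = "covariate")
  .check_mutation(pd, mutation_id)
  .summarize_draws(draws_of(pd, sprintf("beta[%s]", mutation_id)))
}

.interval_draws <- function(pd, mutation_id, age_pair) {
  ages <- pd$parameterization$assay_ages
  age_pair <- sort(as.integer(age_pair))
  if (length(age_pair) != 2L || !all(age_pair %in% ages) ||
      age_pair[1L] == age_pair[2L]) {
    stop("age_pair must be two distinct assay ages", call. = FALSE)
  }
  draws_of(pd, sprintf("phi[%s,%d]", mutation_id, age_pair[2L])) -
    draws_of(pd, sprintf("phi[%s,%d]", mutation_id, age_pair[1L]))
}

#' Interval-specific aging of a mutation
#'
#' Per draw, the mutation's factor-model effect at the later age minus the
#' effect at the earlier age (logit scale); negative values indicate faster
#' mutant aging over that interval.
#'
#' @param pd draws from `fit_aging_model(ds, "factor")`.
#' @param mutation_id mutation label.
#' @param age_pair two distinct assay ages (any order).
#' @return list with `estimate`, `lower`, `upper`, `p_mcmc`.
#' @export
interval_aging <- function(pd, mutation_id, age_pair) {
  .check_model(pd, "aging", age_coding = "factor")
  .check_mutation(pd, mutation_id)
  .summarize_draws(.interval_draws(pd, mutation_id, age_pair))
}

#' Acceleration of reproductive aging
#'
#' Per draw, the aging contrast between the two intervals of the default
#' three-age design: `diff(a2, a3) - diff(a1, a2)` where `diff` is the
#' interval-specific aging above. With negative values meaning faster
#' late-life decline, acceleration (aging rate increasing with age) shows up
#' as a negative contrast.
#'
#' @param pd draws from `fit_aging_model(ds, "factor")` with >= 3 assay ages.
#' @param mutation_id mutation label.
#' @return list with `estimate`, `lower`, `upper`, `p_mcmc`.
#' @export
aging_acceleration <- function(pd, mutation_id) {
  pz <- .check_model(pd, "aging", age_coding = "factor")
  .check_mutation(pd, mutation_id)
  ages <- pz$assay_ages
  if (length(ages) < 3L) {
    stop("design error: acceleration needs >= 3 assay ages", call. = FALSE)
  }
  d_late  <- .interval_draws(pd, mutation_id, ages[2:3])
  d_early <- .interval_draws(pd, mutation_id, ages[1:2])
  .summarize_draws(d_late - d_early)
}

# draws x mutations matrix of factor-model effects at one age
.phi_matrix <- function(pd, age_day, mutation_subset = NULL) {
  pz <- .check_model(pd, "aging", age_coding = "factor")
  if (!age_day %in% pz$assay_ages) {
    stop("lookup error: unknown assay age: ", age_day, call. = FALSE)
  }
  ids <- if (is.null(mutation_subset)) pz$mutation_ids
         else as.character(mutation_subset)
  unknown <- setdiff(ids, pz$mutation_ids)
  if (length(unknown) > 0L) {
    stop("lookup error: unknown mutation(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(ids, function(m) draws_of(pd, sprintf("phi[%s,%d]", m, age_day)),
         numeric(dim(pd$draws)[1L] * dim(pd$draws)[2L]))
}

#' Among-line variance in relative fecundity at one age
#'
#' Per draw, the sample variance (n - 1 denominator) across the subset's
#' factor-model mutation effects at the given age, on the logit/log-ratio
#' scale on which the model is linear.
#'
#' @param pd draws from `fit_aging_model(ds, "factor")`.
#' @param age_day one assay age.
#' @param mutation_subset character vector of >= 2 mutation labels
#'   (default: all).
#' @return list with `estimate`, `lower`, `upper` (no p_mcmc: a variance is
#'   non-negative by construction).
#' @export
among_line_variance <- function(pd, age_day, mutation_subset = NULL) {
  phi <- .phi_matrix(pd, age_day, mutation_subset)
  if (ncol(phi) < 2L) {
    stop("design error: among-line variance needs >= 2 mutations", call. = FALSE)
  }
  v <- apply(phi, 1L, stats::var)
  ci <- .ci95(v)
  list(estimate = mean(v), lower = ci[["lower"]], upper = ci[["upper"]])
}

#' Change in among-line variance between two ages
#'
#' Per draw, the among-line variance at the later age minus the variance at
#' the earlier age; `p_mcmc` tests whether the change differs from 0.
#'
#' @inheritParams among_line_variance
#' @param age_pair two distinct assay ages.
#' @return list with `estimate`, `lower`, `upper`, `p_mcmc`.
#' @export
variance_increase <- function(pd, age_pair, mutation_subset = NULL) {
  age_pair <- sort(as.integer(age_pair))
  if (length(age_pair) != 2L || age_pair[1L] == age_pair[2L]) {
    stop("age_pair must be two distinct assay ages", call. = FALSE)
  }
  phi_e <- .phi_matrix(pd, age_pair[1L], mutation_subset)
  phi_l <- .phi_matrix(pd, age_pair[2L], mutation_subset)
  if (ncol(phi_e) < 2L) {
    stop("design error: among-line variance needs >= 2 mutations", call. = FALSE)
  }
  dv <- apply(phi_l, 1L, stats::var) - apply(phi_e, 1L, stats::var)
  .summarize_draws(dv)
}

# ---- report ----------------------------------------------------------------

#' Per-mutation aging report
#'
#' Assembles the analysis's estimands into one table: deleteriousness from
#' the day-5 and summed Poisson fits, the per-day aging coefficient from the
#' covariate fit, interval-specific aging and the acceleration contrast from
#' the factor fit, plus dataset-level among-line variances. Classification
#' (two-tailed, at `alpha`):
#'
#' * deleterious: day-5 or summed deleteriousness significant with s > 0
#'   (the union rule; which test fired is recorded);
#' * aging: deleterious and the covariate slope significant and negative;
#' * accelerating: aging and the acceleration contrast significant with
#'   faster late-life decline.
#'
#' Any fit may be `NULL`; the corresponding columns are `NA` and the
#' classification uses what is available.
#'
#' @param ds the [fecundity_dataset()] the fits were run on.
#' @param fit_day5,fit_summed [fit_deleteriousness_model()] draws.
#' @param fit_covariate,fit_factor [fit_aging_model()] draws.
#' @param alpha two-tailed significance threshold for classification.
#' @return An object of class `aging_report`: list with `mutations` (one row
#'   per mutation), `variance` (among-line variances and pairwise increases
#'   for the deleterious and aging subsets), `alpha`.
#' @export
aging_report <- function(ds, fit_day5 = NULL, fit_summed = NULL,
                         fit_covariate = NULL, fit_factor = NULL,
                         alpha = 0.05) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  ids <- ds$mutation_ids
  ages <- ds$assay_ages
  n <- length(ids)
  na_col <- rep(NA_real_, n)
  tab <- data.frame(mutation = ids,
                    s_day5 = na_col, s_day5_lower = na_col, s_day5_upper = na_col,
                    s_day5_p = na_col,
                    s_summed = na_col, s_summed_lower = na_col,
                    s_summed_upper = na_col, s_summed_p = na_col,
                    aging_coef = na_col, aging_coef_lower = na_col,
                    aging_coef_upper = na_col, aging_coef_p = na_col,
                    accel = na_col, accel_lower = na_col, accel_upper = na_col,
                    accel_p = na_col,
                    stringsAsFactors = FALSE)
  fill <- function(tab, prefix, fun) {
    for (i in seq_len(n)) {
      z <- fun(ids[i])
      tab[i, paste0(prefix, c("", "_lower", "_upper", "_p"))] <-
        c(z$estimate, z$lower, z$upper, z$p_mcmc)
    }
    tab
  }
  if (!is.null(fit_day5))   tab <- fill(tab, "s_day5",  function(m) deleteriousness(fit_day5, m))
  if (!is.null(fit_summed)) tab <- fill(tab, "s_summed", function(m) deleteriousness(fit_summed, m))
  if (!is.null(fit_covariate)) {
    tab <- fill(tab, "aging_coef", function(m) aging_coefficient(fit_covariate, m))
  }
  if (!is.null(fit_factor) && length(ages) >= 3L) {
    tab <- fill(tab, "accel", function(m) aging_acceleration(fit_factor, m))
    pairs <- list(ages[1:2], ages[2:3], ages[c(1L, 3L)])
    for (pr in pairs) {
      prefix <- sprintf("diff_%d_%d", pr[1L], pr[2L])
      tab[[prefix]] <- na_col
      tab[[paste0(prefix, "_p")]] <- na_col
      for (i in seq_len(n)) {
        z <- interval_aging(fit_factor, ids[i], pr)
        tab[i, prefix] <- z$estimate
        tab[i, paste0(prefix, "_p")] <- z$p_mcmc
      }
    }
  }

  del5  <- !is.na(tab$s_day5_p)  & tab$s_day5_p  < alpha & tab$s_day5 > 0
  delS  <- !is.na(tab$s_summed_p) & tab$s_summed_p < alpha & tab$s_summed > 0
  tab$deleterious_day5   <- del5
  tab$deleterious_summed <- delS
  tab$deleterious <- del5 | delS
  tab$deleterious_by <- ifelse(del5 & delS, "both",
                        ifelse(del5, "day5", ifelse(delS, "summed", "")))
  tab$aging <- tab$deleterious & !is.na(tab$aging_coef_p) &
    tab$aging_coef_p < alpha & tab$aging_coef < 0
  tab$accelerating <- tab$aging & !is.na(tab$accel_p) &
    tab$accel_p < alpha & tab$accel < 0

  variance <- NULL
  if (!is.null(fit_factor) && length(ages) >= 2L) {
    subsets <- list(deleterious = ids[tab$deleterious],
                    aging = ids[tab$aging])
    variance <- lapply(subsets, function(sub) {
      if (length(sub) < 2L) return(NULL)
      at_age <- lapply(ages, function(a) among_line_variance(fit_factor, a, sub))
      names(at_age) <- as.character(ages)
      prs <- utils::combn(ages, 2L, simplify = FALSE)
      incr <- lapply(prs, function(pr) variance_increase(fit_factor, pr, sub))
      names(incr) <- vapply(prs, function(pr) sprintf("%d_%d", pr[1L], pr[2L]), "")
      list(n_lines = length(sub), at_age = at_age, increase = incr)
    })
  }

  structure(list(mutations = tab, variance = variance, alpha = alpha,
                 assay_ages = ages),
            class = "aging_report")
}

#' @export
print.aging_report <- function(x, ...) {
  tab <- x$mutations
  cat("<aging_report>", nrow(tab), "mutations, alpha =", x$alpha, "\n")
  cat(sprintf("  deleterious (day 5): %d   deleterious (union): %d\n",
              sum(tab$deleterious_day5, na.rm = TRUE), sum(tab$deleterious)))
  cat(sprintf("  aging (of deleterious): %d   accelerating (of aging): %d\n",
              sum(tab$aging), sum(tab$accelerating)))
  if (!is.null(x$variance$deleterious)) {
    v <- x$variance$deleterious
    cat("  among-line variance (deleterious subset):",
        paste(sprintf("day %s: %.3f", names(v$at_age),
                      vapply(v$at_age, `[[`, 0, "estimate")), collapse = "  "),
        "\n")
  }
  invisible(x)
}
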