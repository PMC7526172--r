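# Synthetic-data generator emulating the paired vial fecundity assay:
# mutation lines assayed as mutant/wildtype egg counts from matched females
# in shared vials at three adult ages.

#' Configure a synthetic fecundity experiment
#'
#' Defines the generative law for a paired mutant/wildtype vial assay. For
#' mutation m and vial v with shared intercept u_v ~ Normal(0, vial_sd^2):
#'
#' * wildtype eggs at age a ~ Count(exp(mu + gamma_a + u_v))
#' * mutant eggs at age a ~ Count(exp(mu + gamma_a + u_v +
#'     delta_m + beta_m (a - a1) + kappa_m (a - a1)^2))
#'
#' where a1 is the first assay age, so `delta` is the log mutant/wildtype
#' fecundity ratio at the first age (< 0 = deleterious), `beta` the per-day
#' change in that log ratio (< 0 = mutation-induced reproductive aging) and
#' `kappa` a quadratic acceleration term. Count is Poisson, or negative
#' binomial when `overdispersion` (the size/shape parameter) is given.
#'
#' Defaults mirror the experimental design: 20 mutation lines, 20-22 vials
#' per line, fecundity of 25 females per genotype class assayed at adult
#' days 5, 19 and 33.
#'
#' @param n_mutations number of mutation lines.
#' @param vials_per_mutation single integer or inclusive range (length 2);
#'   vial counts per line are drawn uniformly from the range.
#' @param females_per_class laying females per genotype class per vial.
#' @param assay_ages strictly increasing adult ages (days).
#' @param baseline_log_eggs expected log total eggs of one wildtype class at
#'   the first age (default `log(100)`: 4 eggs/female/day for 25 females).
#' @param age_effects wildtype age trajectory gamma_a on the log scale, one
#'   value per assay age (first conventionally 0).
#' @param vial_sd SD of the shared vial random intercept (log scale).
#' @param delta,beta,kappa per-mutation effect vectors (scalars recycled).
#' @param overdispersion optional negative-binomial size; `NULL` = Poisson.
#' @param survival optional list `list(wt_logit =, coupling =, n_start =)`:
#'   day-33 survival is Binomial(n_start, plogis(logit)) per class, with
#'   mutant logit = wt_logit + coupling * delta_m.
#' @param attrition if `TRUE` (requires `survival`), laying females at the
#'   final age are limited to the surviving count, matched across classes.
#' @param seed integer seed making the simulation deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mutations = 20L,
                       vials_per_mutation = c(20L, 22L),
                       females_per_class = 25L,
                       assay_ages = c(5L, 19L, 33L),
                       baseline_log_eggs = log(100),
                       age_effects = c(0, -0.2, -0.6),
                       vial_sd = 0.2,
                       delta = 0,
                       beta = 0,
                       kappa = 0,
                       overdispersion = NULL,
                       survival = NULL,
                       attrition = FALSE,
                       seed = 1L) {
  n_mutations <- as.integer(n_mutations)
  if (is.na(n_mutations) || n_mutations < 1L) {
    stop("config error: n_mutations must be a positive integer", call. = FALSE)
  }
  vials_per_mutation <- as.integer(vials_per_mutation)
  if (!length(vials_per_mutation) %in% 1:2 || anyNA(vials_per_mutation) ||
      any(vials_per_mutation < 1L)) {
    stop("config error: vials_per_mutation must be a positive integer or range",
         call. = FALSE)
  }
  if (length(vials_per_mutation) == 2L &&
      vials_per_mutation[2L] < vials_per_mutation[1L]) {
    stop("config error: vials_per_mutation range must be increasing", call. = FALSE)
  }
  assay_ages <- as.integer(assay_ages)
  if (any(diff(assay_ages) <= 0L)) {
    stop("config error: assay_ages must be strictly increasing", call. = FALSE)
  }
  if (length(age_effects) != length(assay_ages)) {
    stop("config error: age_effects must have one value per assay age", call. = FALSE)
  }
  if (vial_sd < 0) stop("config error: vial_sd must be >= 0", call. = FALSE)
  recycle <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, n_mutations)
    if (length(x) != n_mutations) {
      stop("config error: ", nm, " must have length 1 or n_mutations", call. = FALSE)
    }
    as.numeric(x)
  }
  delta <- recycle(delta, "delta")
  beta  <- recycle(beta, "beta")
  kappa <- recycle(kappa, "kappa")
  if (!is.null(overdispersion) &&
      (!is.numeric(overdispersion) || overdispersion <= 0)) {
    stop("config error: overdispersion must be a positive real or NULL", call. = FALSE)
  }
  if (!is.null(survival)) {
    if (!is.list(survival) || is.null(survival$wt_logit)) {
      stop("config error: survival must be list(wt_logit=, coupling=, n_start=)",
           call. = FALSE)
    }
    if (is.null(survival$coupling)) survival$coupling <- 0
    if (is.null(survival$n_start))  survival$n_start <- 33L
  }
  if (attrition && is.null(survival)) {
    stop("config error: attrition requires a survival specification", call. = FALSE)
  }
  structure(
    list(n_mutations = n_mutations, vials_per_mutation = vials_per_mutation,
         females_per_class = as.integer(females_per_class),
         assay_ages = assay_ages, baseline_log_eggs = baseline_log_eggs,
         age_effects = as.numeric(age_effects), vial_sd = vial_sd,
         delta = delta, beta = beta, kappa = kappa,
         overdispersion = overdispersion, survival = survival,
         attrition = isTRUE(attrition), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Run `fun()` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

#' Simulate a paired fecundity experiment
#'
#' Draws a complete dataset under the generative law of [sim_config()].
#' Deterministic given `config$seed`.
#'
#' @param config a `sim_config`.
#' @return A validated [fecundity_dataset()] (with survival records when the
#'   config specifies them).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config error: expected a sim_config object", call. = FALSE)
  }
  .with_seed(config$seed, function() .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  mut_ids <- sprintf("m%02d", seq_len(cfg$n_mutations))
  a1 <- cfg$assay_ages[1L]
  rows <- vector("list", cfg$n_mutations)
  surv_rows <- vector("list", cfg$n_mutations)
  rcount <- function(n, mean) {
    if (is.null(cfg$overdispersion)) stats::rpois(n, mean)
    else stats::rnbinom(n, size = cfg$overdispersion, mu = mean)
  }
  for (m in seq_len(cfg$n_mutations)) {
    n_vials <- if (length(cfg$vials_per_mutation) == 1L) cfg$vials_per_mutation
               else sample(cfg$vials_per_mutation[1L]:cfg$vials_per_mutation[2L], 1L)
    vial_ids <- sprintf("v%02d", seq_len(n_vials))
    u <- stats::rnorm(n_vials, 0, cfg$vial_sd)

    surv <- NULL
    if (!is.null(cfg$survival)) {
      ns <- cfg$survival$n_start
      p_wt  <- stats::plogis(cfg$survival$wt_logit)
      p_mut <- stats::plogis(cfg$survival$wt_logit +
                             cfg$survival$coupling * cfg$delta[m])
      alive_wt  <- stats::rbinom(n_vials, ns, p_wt)
      alive_mut <- stats::rbinom(n_vials, ns, p_mut)
      last_age <- cfg$assay_ages[length(cfg$assay_ages)]
      surv <- data.frame(
        mutation = mut_ids[m], vial = rep(vial_ids, 2L), age_day = last_age,
        class = rep(c("mut", "wt"), each = n_vials),
        n_alive = c(alive_mut, alive_wt), n_start = ns,
        stringsAsFactors = FALSE)
    }

    mut_rows <- vector("list", length(cfg$assay_ages))
    for (j in seq_along(cfg$assay_ages)) {
      a <- cfg$assay_ages[j]
      nf <- rep(cfg$females_per_class, n_vials)
      if (cfg$attrition && j == length(cfg$assay_ages) && !is.null(surv)) {
        alive_mut <- surv$n_alive[surv$class == "mut"]
        alive_wt  <- surv$n_alive[surv$class == "wt"]
        nf <- pmin(cfg$females_per_class, alive_mut, alive_wt)
      }
      keep <- nf >= 1L
      if (!any(keep)) next
      exposure <- nf[keep] / cfg$females_per_class
      lam_wt <- exp(cfg$baseline_log_eggs + cfg$age_effects[j] + u[keep]) * exposure
      ratio <- exp(cfg$delta[m] + cfg$beta[m] * (a - a1) + cfg$kappa[m] * (a - a1)^2)
      wt_eggs  <- rcount(sum(keep), lam_wt)
      mut_eggs <- rcount(sum(keep), lam_wt * ratio)
      mut_rows[[j]] <- data.frame(
        mutation = mut_ids[m], vial = rep(vial_ids[keep], 2L), age_day = a,
        class = rep(c("mut", "wt"), each = sum(keep)),
        n_females = rep(nf[keep], 2L), eggs = c(mut_eggs, wt_eggs),
        stringsAsFactors = FALSE)
    }
    rows[[m]] <- do.call(rbind, mut_rows)
    surv_rows[[m]] <- surv
  }
  obs <- do.call(rbind, rows)
  surv <- if (!is.null(cfg$survival)) do.call(rbind, surv_rows)
  fecundity_dataset(obs, survival = surv, assay_ages = cfg$assay_ages)
}

#' Simulate a null experiment (all mutation effects zero)
#'
#' Convenience wrapper around [simulate_experiment()] with
#' `delta = beta = kappa = 0`; used for type-I-error calibration.
#'
#' @param n_mutations,n_vials design size.
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A [fecundity_dataset()].
#' @export
simulate_null <- function(n_mutations, n_vials, seed, ...) {
  simulate_experiment(sim_config(
    n_mutations = n_mutations, vials_per_mutation = n_vials,
    delta = 0, beta = 0, kappa = 0, seed = seed, ...))
}

#' Study-shaped simulation configuration
#'
#' A 20-line panel with the effect structure the analysis is designed to
#' detect: 4 neutral lines; 16 deleterious lines with day-5 deleteriousness
#' s spread over 0.10-0.55 (delta = log(1 - s)); the 14 most deleterious of
#' these also age (beta = 0.04 * delta per day, i.e. aging rate proportional
#' to deleteriousness, which makes among-line variance fan out with age);
#' the 10 most deleterious aging lines additionally accelerate
#' (kappa = -8e-4). Day-33 survival is coupled to deleteriousness
#' (logit = 2 + 1.5 * delta) so fecundity-survival pleiotropy is present.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_study <- function(seed = 1L, ...) {
  s_day5 <- c(rep(0, 4L), seq(0.10, 0.55, length.out = 16L))
  delta <- log(1 - s_day5)
  aging <- c(rep(FALSE, 6L), rep(TRUE, 14L))   # 14 most deleterious age
  beta  <- ifelse(aging, 0.04 * delta, 0)
  kappa <- c(rep(0, 10L), rep(-8e-4, 10L))     # 10 most deleterious accelerate
  args <- list(n_mutations = 20L, delta = delta, beta = beta, kappa = kappa,
               survival = list(wt_logit = 2, coupling = 1.5, n_start = 33L),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
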