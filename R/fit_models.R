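# Bayesian hierarchical GLMMs for the paired fecundity assay, fit by MCMC
# through JAGS. Two model families:
#
#  * deleteriousness: vial-level egg count per genotype class,
#    Poisson/log, cell-means per mutation plus a mutant-class effect per
#    mutation (the log mut/wt ratio) and a vial random intercept.
#  * aging: mutant eggs out of (mutant + wildtype) eggs per vial-age,
#    binomial/logit, with age either as a covariate (per-mutation per-day
#    slope) or as a factor (per-mutation per-age cell mean), plus a vial
#    random intercept. Under paired Poisson counts sharing a vial mean,
#    the logit of the binomial success probability equals the log
#    mutant/wildtype rate ratio, so both families estimate the same
#    quantity on their respective scales.
#
# Priors follow the study's convention: Normal(0, 10) for intercept-like
# terms (including cell means), Normal(0, 2.5) for coefficients, with the
# coefficient scale divided by the empirical SD of non-binary predictor
# columns (autoscaling). Default chains: 4 x 4000 iterations, first 1000
# discarded as warm-up.

#' Describe model structure and sampler settings
#'
#' @param family `"poisson-log"` or `"binomial-logit"`.
#' @param age_coding for the binomial family, `"covariate"` or `"factor"`.
#' @param chains number of MCMC chains (>= 2, needed for convergence checks).
#' @param iterations total iterations per chain, including warm-up.
#' @param warmup iterations discarded per chain (adaptation + burn-in).
#' @param prior_intercept_sd,prior_coef_sd Normal prior SDs.
#' @param autoscale divide `prior_coef_sd` by the empirical SD of non-binary
#'   predictor columns.
#' @param rhat_threshold split-R-hat above which a convergence warning is
#'   attached to the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson-log", "binomial-logit"),
                       age_coding = NULL,
                       chains = 4L, iterations = 4000L, warmup = 1000L,
                       prior_intercept_sd = 10, prior_coef_sd = 2.5,
                       autoscale = TRUE, rhat_threshold = 1.05) {
  family <- match.arg(family)
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  warmup <- as.integer(warmup)
  if (chains < 2L) stop("model_spec: chains must be >= 2", call. = FALSE)
  if (warmup >= iterations) {
    stop("model_spec: warmup must be smaller than iterations", call. = FALSE)
  }
  structure(list(family = family, age_coding = age_coding,
                 random_terms = "vial intercept",
                 chains = chains, iterations = iterations, warmup = warmup,
                 prior_intercept_sd = prior_intercept_sd,
                 prior_coef_sd = prior_coef_sd, autoscale = autoscale,
                 rhat_threshold = rhat_threshold),
            class = "model_spec")
}

#' Container for labelled MCMC draws
#'
#' @param draws 3-d numeric array, chains x iterations x parameters, with
#'   parameter names in `dimnames(draws)[[3]]`.
#' @param parameterization list of metadata (model, age coding, centering,
#'   mutation ids, assay ages, ...).
#' @param spec the `model_spec` used (optional).
#' @param rhat optional named vector of split-R-hat values.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, parameterization = list(), spec = NULL,
                            rhat = NULL) {
  if (length(dim(draws)) != 3L) {
    stop("draws must be a chains x iterations x parameters array", call. = FALSE)
  }
  pn <- dimnames(draws)[[3L]]
  if (is.null(pn) || anyDuplicated(pn)) {
    stop("draws must carry unique parameter names", call. = FALSE)
  }
  if (!all(is.finite(draws))) stop("draws contain non-finite values", call. = FALSE)
  structure(list(draws = draws, parameter_names = pn,
                 parameterization = parameterization, spec = spec, rhat = rhat),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<posterior_draws>", d[1L], "chains x", d[2L], "iterations x",
      d[3L], "parameters\n")
  if (!is.null(x$parameterization$model)) {
    cat("  model:", x$parameterization$model,
        if (!is.null(x$parameterization$age_coding))
          paste0("(age as ", x$parameterization$age_coding, ")"), "\n")
  }
  if (!is.null(x$rhat)) cat("  max split R-hat:", round(max(x$rhat), 4), "\n")
  invisible(x)
}

#' Pooled draws of one parameter
#'
#' @param pd a `posterior_draws`.
#' @param parameter parameter name.
#' @return numeric vector pooling all chains.
#' @export
draws_of <- function(pd, parameter) {
  stopifnot(inherits(pd, "posterior_draws"))
  if (!parameter %in% pd$parameter_names) {
    stop("lookup error: unknown parameter: ", parameter, call. = FALSE)
  }
  as.vector(pd$draws[, , parameter])
}

#' @rdname draws_of
#' @export
parameter_names <- function(pd) {
  stopifnot(inherits(pd, "posterior_draws"))
  pd$parameter_names
}

# ---- JAGS plumbing ---------------------------------------------------------

.run_jags <- function(model_string, data, monitors, spec, seed, quiet = TRUE) {
  inits <- lapply(seq_len(spec$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(seed) * 1009L + k) %% 2147483647L + 1L)
  })
  adapt <- max(100L, min(spec$warmup %/% 2L, 1000L))
  burn <- spec$warmup - adapt
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- .quietly(quiet, rjags::jags.model(
    con, data = data, inits = inits, n.chains = spec$chains,
    n.adapt = adapt, quiet = quiet))
  if (burn > 0L) .quietly(quiet, stats::update(jm, burn, progress.bar = "none"))
  samp <- .quietly(quiet, rjags::coda.samples(
    jm, variable.names = monitors, n.iter = spec$iterations - spec$warmup,
    progress.bar = "none"))
  # mcmc.list -> chains x iterations x parameters
  mats <- lapply(samp, function(ch) as.matrix(ch))
  arr <- array(NA_real_, c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])),
               dimnames = list(NULL, NULL, colnames(mats[[1L]])))
  for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
  arr
}

.quietly <- function(quiet, expr) {
  if (quiet) suppressWarnings(suppressMessages(expr)) else expr
}

# JAGS names a monitored vector node "name[i]", but drops the index for a
# length-1 node; map both spellings to "name[<label>]".
.vector_param_map <- function(nodes, labels) {
  map <- character(0)
  for (nd in nodes) {
    map <- c(map, stats::setNames(sprintf("%s[%s]", nd, labels),
                                  sprintf("%s[%d]", nd, seq_along(labels))))
    if (length(labels) == 1L) {
      map <- c(map, stats::setNames(sprintf("%s[%s]", nd, labels), nd))
    }
  }
  map
}

.rename_params <- function(arr, map) {
  pn <- dimnames(arr)[[3L]]
  hit <- pn %in% names(map)
  pn[hit] <- unname(map[pn[hit]])
  dimnames(arr)[[3L]] <- pn
  arr
}

.attach_diagnostics <- function(pd) {
  rh <- gelman_rubin(pd)
  pd$rhat <- rh
  if (max(rh, na.rm = TRUE) > pd$spec$rhat_threshold) {
    warning(sprintf(
      "possible non-convergence: max split R-hat = %.3f (threshold %.2f), worst parameter: %s",
      max(rh, na.rm = TRUE), pd$spec$rhat_threshold, names(which.max(rh))),
      call. = FALSE)
  }
  pd
}

# ---- deleteriousness model -------------------------------------------------

#' Fit the Poisson deleteriousness model
#'
#' Vial-level egg counts per genotype class, Poisson with log link:
#' `log E(eggs) = alpha[mutation] + theta[mutation] * I(class == mut) + u[vial]`,
#' fit either to first-age (day-5) counts only or to counts summed across all
#' assay ages. `theta[m]` is the log mutant/wildtype fecundity ratio of
#' mutation m (the deleteriousness estimand: s = 1 - exp(theta)).
#'
#' @param ds a [fecundity_dataset()] with >= 1 mutation having >= 2 vials.
#' @param ages_used `"first"` (first assay age only) or `"summed"` (counts
#'   summed across available assay ages; vials missing an age are summed over
#'   the ages present and flagged with a message).
#' @param spec a [model_spec()]; defaults to the study's sampler settings.
#' @param seed integer seed for the MCMC RNG streams.
#' @param quiet suppress sampler progress output.
#' @return A [posterior_draws()] with parameters `alpha[<mutation>]`,
#'   `theta[<mutation>]` and `sigma_vial`, split-R-hat attached.
#' @export
fit_deleteriousness_model <- function(ds, ages_used = c("first", "summed"),
                                      spec = model_spec("poisson-log"),
                                      seed = 1L, quiet = TRUE) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  ages_used <- match.arg(ages_used)
  obs <- ds$observations
  if (ages_used == "first") {
    obs <- obs[obs$age_day == ds$assay_ages[1L], ]
    y <- obs$eggs
    keydf <- obs[c("mutation", "vial", "class")]
  } else {
    key <- paste(obs$mutation, obs$vial, obs$class, sep = "\r")
    agg <- tapply(obs$eggs, key, sum)
    n_ages <- tapply(obs$age_day, key, function(a) length(unique(a)))
    if (any(n_ages < length(ds$assay_ages))) {
      message(sum(n_ages < length(ds$assay_ages)),
              " vial-class series missing an assay age; summed over available ages")
    }
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    keydf <- data.frame(mutation = parts[, 1L], vial = parts[, 2L],
                        class = parts[, 3L], stringsAsFactors = FALSE)
    y <- as.integer(agg)
  }
  vials_per_mut <- tapply(keydf$vial, keydf$mutation,
                          function(v) length(unique(v)))
  if (max(vials_per_mut) < 2L) {
    stop("design error: need at least one mutation with >= 2 vials", call. = FALSE)
  }

  mut_ids <- ds$mutation_ids
  mut <- match(keydf$mutation, mut_ids)
  vial_key <- paste(keydf$mutation, keydf$vial, sep = "\r")
  vial_levels <- unique(vial_key)
  vial <- match(vial_key, vial_levels)

  # Hierarchically centered vial intercepts (vial means drawn around their
  # mutation's mean): egg counts pin each vial's level tightly, and this
  # form keeps the mutation mean and the vial effects from trading off in
  # the Gibbs updates.
  mstr <- "
model {
  for (i in 1:N) {
    y[i] ~ dpois(lam[i])
    log(lam[i]) <- v[vial[i]] + theta[mut[i]] * is_mut[i]
  }
  for (j in 1:V) { v[j] ~ dnorm(alpha[mut_of_vial[j]], tau_u) }
  for (m in 1:M) {
    alpha[m] ~ dnorm(0, prec_int)
    theta[m] ~ dnorm(0, prec_coef)
  }
  sigma_vial ~ dt(0, prec_sd, 1) T(0,)
  tau_u <- pow(sigma_vial, -2)
}"
  mut_of_vial <- mut[match(vial_levels, vial_key)]
  data <- list(y = y, mut = mut, is_mut = as.integer(keydf$class == "mut"),
               vial = vial, mut_of_vial = mut_of_vial,
               N = length(y), M = length(mut_ids),
               V = length(vial_levels),
               prec_int = 1 / spec$prior_intercept_sd^2,
               prec_coef = 1 / spec$prior_coef_sd^2,  # binary column: no rescaling
               prec_sd = 1 / 2.5^2)
  arr <- .run_jags(mstr, data, c("alpha", "theta", "sigma_vial"), spec, seed, quiet)
  arr <- .rename_params(arr, .vector_param_map(c("alpha", "theta"), mut_ids))
  pd <- posterior_draws(
    arr,
    parameterization = list(model = "deleteriousness", family = "poisson-log",
                            ages_used = ages_used, mutation_ids = mut_ids,
                            assay_ages = ds$assay_ages,
                            coding = "cell means + mutant-class effect",
                            vial_intercept = "hierarchically centered"),
    spec = spec)
  .attach_diagnostics(pd)
}

# ---- aging models ----------------------------------------------------------

#' Fit the binomial aging model
#'
#' Per (mutation, vial, age), mutant eggs out of (mutant + wildtype) eggs,
#' binomial with logit link. With paired Poisson counts sharing a vial mean,
#' logit(p) equals the log mutant/wildtype rate ratio, so the model tracks
#' the age trajectory of relative fecundity directly.
#'
#' * `age_coding = "covariate"`:
#'   `logit(p) = eta[mutation] + beta[mutation] * (age - first_age) + u[vial]`;
#'   `beta[m]` is the per-day rate of reproductive aging of mutation m
#'   (negative = mutant fecundity declines faster than wildtype).
#' * `age_coding = "factor"`:
#'   `logit(p) = phi[mutation, age] + u[vial]`; cell means per mutation-age,
#'   from which interval differences, acceleration contrasts and among-line
#'   variances are derived.
#'
#' The vial intercept is non-centered (`sigma_vial * z[vial]`, `z ~ N(0,1)`),
#' which mixes well when the vial effect on the mutant/wildtype ratio is
#' near zero, as the paired design makes likely. Vial-age pairs with zero
#' total eggs are dropped with a message (a binomial trial of size 0 carries
#' no information).
#'
#' @param ds a [fecundity_dataset()] with paired counts at >= 2 assay ages.
#' @param age_coding `"covariate"` or `"factor"`.
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @param quiet suppress sampler output.
#' @return A [posterior_draws()]; parameters `eta[<mutation>]`,
#'   `beta[<mutation>]` (covariate) or `phi[<mutation>,<age>]` (factor),
#'   plus `sigma_vial`.
#' @export
fit_aging_model <- function(ds, age_coding = c("covariate", "factor"),
                            spec = NULL, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  age_coding <- match.arg(age_coding)
  if (is.null(spec)) spec <- model_spec("binomial-logit", age_coding = age_coding)
  if (length(ds$assay_ages) < 2L) {
    stop("design error: aging models need >= 2 assay ages", call. = FALSE)
  }
  pc <- paired_counts(ds)
  ntot <- pc$mut_eggs + pc$wt_eggs
  drop <- ntot == 0L
  if (any(drop)) {
    message(sum(drop), " vial-age pair(s) with zero total eggs dropped")
    pc <- pc[!drop, ]; ntot <- ntot[!drop]
  }
  if (length(unique(pc$age_day)) < 2L) {
    stop("design error: aging models need >= 2 assay ages with data", call. = FALSE)
  }

  mut_ids <- ds$mutation_ids
  mut <- match(pc$mutation, mut_ids)
  vial_key <- paste(pc$mutation, pc$vial, sep = "\r")
  vial_levels <- unique(vial_key)
  vial <- match(vial_key, vial_levels)
  a1 <- ds$assay_ages[1L]

  if (age_coding == "covariate") {
    aged <- pc$age_day - a1
    sd_age <- stats::sd(aged)
    coef_sd <- if (isTRUE(spec$autoscale) && sd_age > 0) {
      spec$prior_coef_sd / sd_age
    } else spec$prior_coef_sd
    mstr <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], ntot[i])
    logit(p[i]) <- eta[mut[i]] + beta[mut[i]] * aged[i] + sigma_vial * z[vial[i]]
  }
  for (m in 1:M) {
    eta[m] ~ dnorm(0, prec_int)
    beta[m] ~ dnorm(0, prec_coef)
  }
  for (v in 1:V) { z[v] ~ dnorm(0, 1) }
  sigma_vial ~ dt(0, prec_sd, 1) T(0,)
}"
    data <- list(y = pc$mut_eggs, ntot = ntot, mut = mut, aged = aged,
                 vial = vial, N = nrow(pc), M = length(mut_ids),
                 V = length(vial_levels),
                 prec_int = 1 / spec$prior_intercept_sd^2,
                 prec_coef = 1 / coef_sd^2, prec_sd = 1 / 2.5^2)
    arr <- .run_jags(mstr, data, c("eta", "beta", "sigma_vial"), spec, seed, quiet)
    arr <- .rename_params(arr, .vector_param_map(c("eta", "beta"), mut_ids))
    param_meta <- list(age_centering = a1, coef_prior_sd = coef_sd)
  } else {
    ai <- match(pc$age_day, ds$assay_ages)
    mstr <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], ntot[i])
    logit(p[i]) <- phi[mut[i], ai[i]] + sigma_vial * z[vial[i]]
  }
  for (m in 1:M) { for (a in 1:A) { phi[m, a] ~ dnorm(0, prec_int) } }
  for (v in 1:V) { z[v] ~ dnorm(0, 1) }
  sigma_vial ~ dt(0, prec_sd, 1) T(0,)
}"
    data <- list(y = pc$mut_eggs, ntot = ntot, mut = mut, ai = ai,
                 vial = vial, N = nrow(pc), M = length(mut_ids),
                 A = length(ds$assay_ages), V = length(vial_levels),
                 prec_int = 1 / spec$prior_intercept_sd^2,
                 prec_sd = 1 / 2.5^2)
    arr <- .run_jags(mstr, data, c("phi", "sigma_vial"), spec, seed, quiet)
    grid <- expand.grid(m = seq_along(mut_ids), a = seq_along(ds$assay_ages))
    map <- stats::setNames(
      sprintf("phi[%s,%d]", mut_ids[grid$m], ds$assay_ages[grid$a]),
      sprintf("phi[%d,%d]", grid$m, grid$a))
    arr <- .rename_params(arr, map)
    param_meta <- list()
  }
  pd <- posterior_draws(
    arr,
    parameterization = c(list(model = "aging", family = "binomial-logit",
                              age_coding = age_coding, mutation_ids = mut_ids,
                              assay_ages = ds$assay_ages,
                              vial_intercept = "non-centered",
                              dropped_zero_total = sum(drop)),
                         param_meta),
    spec = spec)
  .attach_diagnostics(pd)
}

# ---- convergence diagnostic ------------------------------------------------

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half and the PSRF computed over the resulting
#' half-chains: `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean
#' within-sequence variance and `B` the between-sequence variance of the
#' half-chain means. Values near 1 indicate convergence; 1.05 is the working
#' threshold.
#'
#' @param x a [posterior_draws()], a chains x iterations x parameters array,
#'   or a list of iterations x parameters matrices (one per chain).
#' @return Named numeric vector of split-R-hat values, one per parameter.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "posterior_draws")) x <- x$draws
  if (is.list(x) && !is.array(x)) {
    mats <- lapply(x, as.matrix)
    x <- array(NA_real_, c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])),
               dimnames = list(NULL, NULL, colnames(mats[[1L]])))
    for (k in seq_along(mats)) x[k, , ] <- mats[[k]]
  }
  if (length(dim(x)) != 3L) {
    stop("expected chains x iterations x parameters draws", call. = FALSE)
  }
  n_chain <- dim(x)[1L]; n_iter <- dim(x)[2L]
  if (n_chain < 2L) {
    stop("gelman_rubin requires at least 2 chains", call. = FALSE)
  }
  half <- n_iter %/% 2L
  if (half < 2L) stop("chains too short to split", call. = FALSE)
  pn <- dimnames(x)[[3L]]
  out <- vapply(seq_len(dim(x)[3L]), function(j) {
    seqs <- vector("list", 2L * n_chain)
    for (k in seq_len(n_chain)) {
      seqs[[2L * k - 1L]] <- x[k, seq_len(half), j]
      seqs[[2L * k]]      <- x[k, half + seq_len(half), j]
    }
    means <- vapply(seqs, mean, 0)
    vars  <- vapply(seqs, stats::var, 0)
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
  stats::setNames(out, pn %||% sprintf("param%d", seq_along(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
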