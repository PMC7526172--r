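# Shared helpers: fast (non-publication-grade) sampler settings, tiny
# dataset builders, and a cache so expensive fits are shared across tests.

fast_spec <- function(family, age_coding = NULL,
                      chains = 2L, iterations = 900L, warmup = 300L) {
  model_spec(family, age_coding = age_coding, chains = chains,
             iterations = iterations, warmup = warmup)
}

# two-row-per-vial-age toy observations table
toy_obs <- function(mut_eggs = 50L, wt_eggs = 60L, mutation = "A", vial = "1",
                    age_day = 5L, n_females = 25L) {
  data.frame(
    mutation = mutation, vial = vial, age_day = age_day,
    class = c("mut", "wt"), n_females = n_females,
    eggs = c(mut_eggs, wt_eggs), stringsAsFactors = FALSE)
}

# dataset with explicit per-vial counts at one age
toy_dataset <- function(mut_eggs, wt_eggs, age_day = 5L) {
  obs <- do.call(rbind, lapply(seq_along(mut_eggs), function(v) {
    toy_obs(mut_eggs[v], wt_eggs[v], vial = as.character(v), age_day = age_day)
  }))
  fecundity_dataset(obs)
}

# brute-force Kendall oracle: explicit double loop over all pairs
oracle_tau_b <- function(x, y) {
  n <- length(x)
  S <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx != 0 && dy != 0) S <- S + sign(dx) * sign(dy)
    }
  }
  n0 <- n * (n - 1) / 2
  if (n0 - tx == 0 || n0 - ty == 0) return(list(S = S, tau = NA_real_))
  list(S = S, tau = S / sqrt((n0 - tx) * (n0 - ty)))
}

# oracle exact two-tailed p by enumerating permutations of y (recursively,
# independent of the package's permutation generator)
oracle_exact_p <- function(x, y) {
  obs <- oracle_tau_b(x, y)$S
  S_all <- numeric(0)
  recurse <- function(chosen, remaining) {
    if (length(remaining) == 0) {
      S_all[length(S_all) + 1] <<- oracle_tau_b(x, chosen)$S
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      recurse(c(chosen, remaining[k]), remaining[-k])
    }
  }
  recurse(numeric(0), y)
  min(1, 2 * min(mean(S_all <= obs), mean(S_all >= obs)))
}

# memoised expensive objects, shared across test files within one run
.fit_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fit_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fit_cache)
  }
  get(name, envir = .fit_cache, inherits = FALSE)
}
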