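# Rank-correlation suite for age pleiotropy: associations between a
# mutation's median relative fecundity at different ages, between its
# deleteriousness and the aging it induces, and between fecundity and
# survival effects.

.resolve_subset <- function(ds, mutation_subset) {
  ids <- if (is.null(mutation_subset)) ds$mutation_ids
         else as.character(mutation_subset)
  unknown <- setdiff(ids, ds$mutation_ids)
  if (length(unknown) > 0L) {
    stop("lookup error: unknown mutation(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids
}

.resolve_pair <- function(ds, age_pair) {
  age_pair <- sort(as.integer(age_pair))
  if (length(age_pair) != 2L || !all(age_pair %in% ds$assay_ages) ||
      age_pair[1L] == age_pair[2L]) {
    stop("age_pair must be two distinct assay ages", call. = FALSE)
  }
  age_pair
}

#' Fecundity-fecundity pleiotropy between two ages
#'
#' Kendall's tau-b between the per-mutation median relative fecundities
#' (ln\[mut/wt\], +1 offset) at the two ages. A positive tau is positive
#' pleiotropy: mutations harmful at one age are harmful at the other.
#'
#' @param ds a [fecundity_dataset()].
#' @param mutation_subset >= 3 mutation labels (default: all).
#' @param age_pair two distinct assay ages.
#' @return A [kendall_tau()] `tau_result`.
#' @export
age_pleiotropy <- function(ds, mutation_subset = NULL, age_pair) {
  ids <- .resolve_subset(ds, mutation_subset)
  age_pair <- .resolve_pair(ds, age_pair)
  med <- fecundity_medians(ds, ids)
  kendall_tau(med[, as.character(age_pair[1L])],
              med[, as.character(age_pair[2L])])
}

#' Association between deleteriousness and induced aging
#'
#' Per mutation, the change in median relative fecundity between the two
#' ages (later minus earlier) is correlated (Kendall's tau-b) with the
#' median relative fecundity at the earlier age. A positive tau means more
#' deleterious mutations (lower level) induce faster aging (more negative
#' change).
#'
#' Note the built-in conservativeness: sampling error in the earlier-age
#' median enters the change with opposite sign, biasing the association
#' towards negative values; with pure noise the expected tau is below 0,
#' not 0.
#'
#' @inheritParams age_pleiotropy
#' @return A `tau_result`.
#' @export
aging_vs_deleteriousness <- function(ds, mutation_subset = NULL, age_pair) {
  ids <- .resolve_subset(ds, mutation_subset)
  age_pair <- .resolve_pair(ds, age_pair)
  med <- fecundity_medians(ds, ids)
  level <- med[, as.character(age_pair[1L])]
  change <- med[, as.character(age_pair[2L])] - level
  kendall_tau(level, change)
}

#' Fecundity-survival pleiotropy
#'
#' Kendall's tau-b between the median relative fecundity at the first assay
#' age and the relative survival ln\[(mut + 1)/(wt + 1)\] at the final assay
#' age, one value per mutation. Survivors are pooled across vials by default
#' (`method = "pooled"`); `"vial_median"` instead takes the median of the
#' per-vial log survival ratios.
#'
#' @param ds a [fecundity_dataset()] carrying survival records at its final
#'   assay age.
#' @param mutation_subset >= 3 mutation labels (default: all).
#' @param method survivor aggregation across vials.
#' @return A `tau_result`.
#' @export
survival_pleiotropy <- function(ds, mutation_subset = NULL,
                                method = c("pooled", "vial_median")) {
  method <- match.arg(method)
  ids <- .resolve_subset(ds, mutation_subset)
  last_age <- ds$assay_ages[length(ds$assay_ages)]
  surv <- ds$survival
  if (is.null(surv) || !any(surv$age_day == last_age)) {
    stop("missing survival records at the final assay age", call. = FALSE)
  }
  surv <- surv[surv$age_day == last_age & surv$mutation %in% ids, ]
  ratio <- vapply(ids, function(m) {
    sm <- surv[surv$mutation == m, ]
    am <- sm[sm$class == "mut", c("vial", "n_alive")]
    aw <- sm[sm$class == "wt",  c("vial", "n_alive")]
    if (nrow(am) == 0L || nrow(aw) == 0L) {
      stop("missing survival records for mutation ", m, call. = FALSE)
    }
    if (method == "pooled") {
      log((sum(am$n_alive) + 1) / (sum(aw$n_alive) + 1))
    } else {
      both <- merge(am, aw, by = "vial", suffixes = c("_mut", "_wt"))
      stats::median(log((both$n_alive_mut + 1) / (both$n_alive_wt + 1)))
    }
  }, 0)
  fec <- fecundity_medians(ds, ids)[, as.character(ds$assay_ages[1L])]
  kendall_tau(fec, ratio)
}
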