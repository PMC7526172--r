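# Data model for the paired mutant/wildtype fecundity assay.
#
# The atomic record is one (mutation line, vial, age-day, genotype class)
# egg count from 24 h of laying by n_females females. Records come in
# mutant/wildtype pairs within a vial-age, with matched n_females.

.CANONICAL_OBS  <- c("mutation", "vial", "age_day", "class", "n_females", "eggs")
.CANONICAL_SURV <- c("mutation", "vial", "age_day", "class", "n_alive", "n_start")

#' Construct and validate a fecundity dataset
#'
#' Bundles vial-level egg-count observations (and optional survival records)
#' into a validated container used by all model-fitting and correlation
#' functions. Validation enforces the paired design: for every
#' (mutation, vial, age) there must be exactly one mutant and one wildtype
#' record, with equal numbers of laying females.
#'
#' @param observations data frame with columns `mutation`, `vial`, `age_day`,
#'   `class` (`"mut"` or `"wt"`), `n_females` (>= 1) and `eggs` (>= 0).
#' @param survival optional data frame with columns `mutation`, `vial`,
#'   `age_day`, `class`, `n_alive`, `n_start` (0 <= n_alive <= n_start).
#' @param assay_ages strictly increasing integer vector of assay ages in adult
#'   days; defaults to the sorted ages present in `observations`.
#' @return An object of class `fecundity_dataset`: a list with elements
#'   `observations`, `survival`, `assay_ages` and `mutation_ids`.
#' @export
fecundity_dataset <- function(observations, survival = NULL, assay_ages = NULL) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  miss <- setdiff(.CANONICAL_OBS, names(obs))
  if (length(miss) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  obs <- obs[.CANONICAL_OBS]
  obs$mutation  <- as.character(obs$mutation)
  obs$vial      <- as.character(obs$vial)
  obs$age_day   <- as.integer(obs$age_day)
  obs$class     <- .normalize_class(obs$class)
  obs$n_females <- as.integer(obs$n_females)
  obs$eggs      <- as.integer(obs$eggs)

  if (anyNA(obs$eggs) || any(obs$eggs < 0L)) {
    stop("value error: egg counts must be non-negative integers", call. = FALSE)
  }
  if (anyNA(obs$n_females) || any(obs$n_females < 1L)) {
    stop("value error: n_females must be a positive integer", call. = FALSE)
  }
  if (anyNA(obs$age_day)) stop("value error: age_day must be integer", call. = FALSE)

  if (is.null(assay_ages)) assay_ages <- sort(unique(obs$age_day))
  assay_ages <- as.integer(assay_ages)
  if (length(assay_ages) < 1L || anyNA(assay_ages) ||
      any(diff(assay_ages) <= 0L)) {
    stop("assay_ages must be a strictly increasing integer vector", call. = FALSE)
  }
  if (!all(obs$age_day %in% assay_ages)) {
    stop("value error: age_day outside assay_ages: ",
         paste(setdiff(unique(obs$age_day), assay_ages), collapse = ", "),
         call. = FALSE)
  }

  .check_pairing(obs)

  if (!is.null(survival)) survival <- .validate_survival(survival)

  obs <- obs[order(obs$mutation, obs$vial, obs$age_day, obs$class), ]
  rownames(obs) <- NULL
  structure(
    list(observations = obs,
         survival     = survival,
         assay_ages   = assay_ages,
         mutation_ids = sort(unique(obs$mutation))),
    class = "fecundity_dataset"
  )
}

.normalize_class <- function(x) {
  x <- as.character(x)
  x[x %in% c("mutant", "m")]   <- "mut"
  x[x %in% c("wildtype", "w")] <- "wt"
  if (!all(x %in% c("mut", "wt"))) {
    stop("value error: class must be 'mut' or 'wt' (got: ",
         paste(setdiff(unique(x), c("mut", "wt")), collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

# Paired-design invariant: exactly one mut and one wt record per
# (mutation, vial, age), with matched n_females.
.check_pairing <- function(obs) {
  key <- paste(obs$mutation, obs$vial, obs$age_day, sep = "\r")
  n_mut <- tapply(obs$class == "mut", key, sum)
  n_wt  <- tapply(obs$class == "wt",  key, sum)
  bad <- names(n_mut)[n_mut != 1L | n_wt != 1L]
  if (length(bad) > 0L) {
    parts <- strsplit(bad[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "pairing error: mutation %s, vial %s, day %s does not have exactly one mutant and one wildtype record (%d offending vial-age(s) in total)",
      parts[1L], parts[2L], parts[3L], length(bad)), call. = FALSE)
  }
  n_uniq <- tapply(obs$n_females, key, function(z) length(unique(z)))
  bad <- names(n_uniq)[n_uniq > 1L]
  if (length(bad) > 0L) {
    parts <- strsplit(bad[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "pairing error: mutation %s, vial %s, day %s has unequal n_females across genotype classes",
      parts[1L], parts[2L], parts[3L]), call. = FALSE)
  }
  invisible(TRUE)
}

.validate_survival <- function(survival) {
  surv <- as.data.frame(survival, stringsAsFactors = FALSE)
  miss <- setdiff(.CANONICAL_SURV, names(surv))
  if (length(miss) > 0L) {
    stop("schema error: survival table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  surv <- surv[.CANONICAL_SURV]
  surv$mutation <- as.character(surv$mutation)
  surv$vial     <- as.character(surv$vial)
  surv$age_day  <- as.integer(surv$age_day)
  surv$class    <- .normalize_class(surv$class)
  surv$n_alive  <- as.integer(surv$n_alive)
  surv$n_start  <- as.integer(surv$n_start)
  if (anyNA(surv$n_alive) || anyNA(surv$n_start) ||
      any(surv$n_alive < 0L) || any(surv$n_start < 1L) ||
      any(surv$n_alive > surv$n_start)) {
    stop("value error: survival records need 0 <= n_alive <= n_start", call. = FALSE)
  }
  surv <- surv[order(surv$mutation, surv$vial, surv$age_day, surv$class), ]
  rownames(surv) <- NULL
  surv
}

#' @export
print.fecundity_dataset <- function(x, ...) {
  obs <- x$observations
  n_vials <- length(unique(paste(obs$mutation, obs$vial)))
  cat("<fecundity_dataset>\n")
  cat("  mutations: ", length(x$mutation_ids),
      "   vials: ", n_vials,
      "   assay ages (days): ", paste(x$assay_ages, collapse = ", "), "\n", sep = "")
  cat("  observations: ", nrow(obs),
      if (is.null(x$survival)) "   (no survival records)\n"
      else sprintf("   survival records: %d\n", nrow(x$survival)), sep = "")
  invisible(x)
}

#' Read a fecundity dataset from delimited text
#'
#' Reads a CSV with one row per (mutation, vial, age, class) egg-count record,
#' optionally together with a survival CSV, and returns a validated
#' [fecundity_dataset()]. Column names can be remapped via `schema` to
#' tolerate externally produced headers.
#'
#' @param path path to the observations CSV.
#' @param schema optional named character vector mapping canonical column names
#'   (`mutation`, `vial`, `age_day`, `class`, `n_females`, `eggs`) to the
#'   file's headers, e.g. `c(eggs = "egg_count")`.
#' @param survival_path optional path to a survival CSV with canonical columns
#'   `mutation`, `vial`, `age_day`, `class`, `n_alive`, `n_start`.
#' @param survival_schema optional column mapping for the survival file.
#' @return A validated `fecundity_dataset`.
#' @export
load_fecundity_table <- function(path, schema = NULL,
                                 survival_path = NULL, survival_schema = NULL) {
  obs <- .read_mapped(path, schema, .CANONICAL_OBS)
  surv <- if (!is.null(survival_path)) {
    .read_mapped(survival_path, survival_schema, .CANONICAL_SURV)
  }
  fecundity_dataset(obs, survival = surv)
}

.read_mapped <- function(path, schema, canonical) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || !all(names(schema) %in% canonical)) {
      stop("schema error: schema names must be canonical column names", call. = FALSE)
    }
    absent <- schema[!(schema %in% names(raw))]
    if (length(absent) > 0L) {
      stop("schema error: mapped column(s) not in file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (canon in names(schema)) names(raw)[names(raw) == schema[[canon]]] <- canon
  }
  miss <- setdiff(canonical, names(raw))
  if (length(miss) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw
}

#' Write a fecundity dataset to CSV
#'
#' Inverse of [load_fecundity_table()]: `load(write(ds))` reproduces `ds`
#' field by field.
#'
#' @param ds a `fecundity_dataset`.
#' @param path output path for the observations CSV.
#' @param survival_path optional output path for the survival CSV.
#' @return `ds`, invisibly.
#' @export
write_fecundity_table <- function(ds, path, survival_path = NULL) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  utils::write.csv(ds$observations, path, row.names = FALSE, quote = FALSE)
  if (!is.null(survival_path)) {
    if (is.null(ds$survival)) stop("dataset has no survival records", call. = FALSE)
    utils::write.csv(ds$survival, survival_path, row.names = FALSE, quote = FALSE)
  }
  invisible(ds)
}

#' Per-vial relative fecundity, ln((mut + 1) / (wt + 1))
#'
#' The log ratio of mutant to wildtype egg counts with 1 added to all counts,
#' so vials where one class laid no eggs remain finite. Vectorized.
#'
#' @param mut_eggs,wt_eggs non-negative integer vectors.
#' @return numeric vector of log ratios.
#' @export
relative_fecundity <- function(mut_eggs, wt_eggs) {
  if (any(mut_eggs < 0) || any(wt_eggs < 0)) {
    stop("value error: egg counts must be non-negative", call. = FALSE)
  }
  log((mut_eggs + 1) / (wt_eggs + 1))
}

# Long-to-paired reshape: one row per (mutation, vial, age) with both
# class counts and the per-vial relative fecundity.
#' Paired per-vial counts and relative fecundity
#'
#' @param ds a `fecundity_dataset`.
#' @return data frame with columns `mutation`, `vial`, `age_day`, `mut_eggs`,
#'   `wt_eggs`, `n_females`, `rel_fec`.
#' @export
paired_counts <- function(ds) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  obs <- ds$observations
  m <- obs[obs$class == "mut", c("mutation", "vial", "age_day", "n_females", "eggs")]
  w <- obs[obs$class == "wt",  c("mutation", "vial", "age_day", "eggs")]
  names(m)[names(m) == "eggs"] <- "mut_eggs"
  names(w)[names(w) == "eggs"] <- "wt_eggs"
  out <- merge(m, w, by = c("mutation", "vial", "age_day"), sort = TRUE)
  out$rel_fec <- relative_fecundity(out$mut_eggs, out$wt_eggs)
  out[order(out$mutation, out$vial, out$age_day),
      c("mutation", "vial", "age_day", "mut_eggs", "wt_eggs", "n_females", "rel_fec")]
}

#' Median relative fecundity of one mutation at one age
#'
#' Median across replicate vials of the per-vial ln((mut+1)/(wt+1)).
#'
#' @param ds a `fecundity_dataset`.
#' @param mutation_id mutation label present in `ds`.
#' @param age_day one of the dataset's assay ages.
#' @return scalar median log ratio.
#' @export
median_relative_fecundity <- function(ds, mutation_id, age_day) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  if (!mutation_id %in% ds$mutation_ids) {
    stop("lookup error: unknown mutation: ", mutation_id, call. = FALSE)
  }
  if (!age_day %in% ds$assay_ages) {
    stop("lookup error: unknown assay age: ", age_day, call. = FALSE)
  }
  pc <- paired_counts(ds)
  v <- pc$rel_fec[pc$mutation == mutation_id & pc$age_day == age_day]
  if (length(v) == 0L) {
    stop("lookup error: no paired vials for mutation ", mutation_id,
         " at day ", age_day, call. = FALSE)
  }
  stats::median(v)
}

#' Matrix of median relative fecundities (mutations x assay ages)
#'
#' @param ds a `fecundity_dataset`.
#' @param mutation_subset optional character vector of mutation labels.
#' @return numeric matrix, rows = mutations, columns = assay ages (as
#'   character day labels). `NA` where a mutation has no paired vial at an age.
#' @export
fecundity_medians <- function(ds, mutation_subset = NULL) {
  stopifnot(inherits(ds, "fecundity_dataset"))
  ids <- if (is.null(mutation_subset)) ds$mutation_ids else as.character(mutation_subset)
  unknown <- setdiff(ids, ds$mutation_ids)
  if (length(unknown) > 0L) {
    stop("lookup error: unknown mutation(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pc <- paired_counts(ds)
  out <- matrix(NA_real_, length(ids), length(ds$assay_ages),
                dimnames = list(ids, as.character(ds$assay_ages)))
  for (i in seq_along(ids)) {
    for (j in seq_along(ds$assay_ages)) {
      v <- pc$rel_fec[pc$mutation == ids[i] & pc$age_day == ds$assay_ages[j]]
      if (length(v) > 0L) out[i, j] <- stats::median(v)
    }
  }
  out
}
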