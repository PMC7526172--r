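# Kendall rank correlation with tie correction (tau-b) and small-sample
# exact two-tailed p values. Medians of log fecundity ratios can tie
# (notably the +1-offset zeros), so tie handling is first-class here.

#' Kendall's tau-b with a two-tailed p value
#'
#' Computes the tie-corrected rank correlation
#' `tau_b = S / sqrt((n0 - Tx)(n0 - Ty))` where `S` is the number of
#' concordant minus discordant pairs, `n0 = n(n-1)/2`, and `Tx`, `Ty` count
#' tied pairs within each variable. Without ties this coincides with the
#' plain (tau-a) statistic.
#'
#' Two-tailed p value against the null of no association:
#' * exact, untied data with n <= 10: the closed-form permutation null of
#'   `S` (inversion-count recursion over all n! orderings);
#' * exact, tied data with n <= 8: full enumeration of the n! permutations
#'   of `y` (tie pattern fixed, so the `S` null is exact);
#' * otherwise: normal approximation with the tie-corrected variance of
#'   `S`, no continuity correction.
#'
#' If all values of either variable are tied, tau is undefined; the result
#' carries `degenerate = TRUE` with `tau = NA`.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @param p_method `"auto"` (the switch above), `"exact"` or `"approx"`.
#' @return An object of class `tau_result`: list with `tau`, `p_two_tailed`,
#'   `n`, `method` (`"exact"` or `"approximation"`), `S`, `degenerate`.
#' @export
kendall_tau <- function(x, y, p_method = c("auto", "exact", "approx")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) {
    stop("kendall_tau: x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("kendall_tau: need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("kendall_tau: non-finite values", call. = FALSE)
  }

  S <- .kendall_S(x, y)
  n0 <- n * (n - 1) / 2
  Tx <- .tie_pairs(x); Ty <- .tie_pairs(y)
  degenerate <- (n0 - Tx) == 0 || (n0 - Ty) == 0
  tau <- if (degenerate) NA_real_ else S / sqrt((n0 - Tx) * (n0 - Ty))

  has_ties <- Tx > 0 || Ty > 0
  use_exact <- switch(p_method,
    exact = TRUE, approx = FALSE,
    auto = (!has_ties && n <= 10L) || (has_ties && n <= 8L))
  if (degenerate) {
    p <- NA_real_
    method <- "degenerate"
  } else if (use_exact) {
    p <- if (has_ties) .kendall_exact_ties(x, y, S) else .kendall_exact_free(n, S)
    method <- "exact"
  } else {
    p <- .kendall_approx(x, y, S)
    method <- "approximation"
  }
  structure(list(tau = tau, p_two_tailed = p, n = n, method = method,
                 S = S, degenerate = degenerate),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %s, two-tailed p = %s (n = %d, %s)%s\n",
              format(round(x$tau, 4)), format(signif(x$p_two_tailed, 4)),
              x$n, x$method,
              if (x$degenerate) " [degenerate: all values tied]" else ""))
  invisible(x)
}

# concordant minus discordant pairs
.kendall_S <- function(x, y) {
  d <- sign(outer(x, x, "-")) * sign(outer(y, y, "-"))
  sum(d[upper.tri(d)])
}

.tie_pairs <- function(x) {
  t <- table(x)
  sum(t * (t - 1) / 2)
}

# Exact null of S for untied data: distribution of concordance over the n!
# orderings via the inversion-count recursion (number of permutations of
# 1..k with a given number of inversions).
.kendall_exact_free <- function(n, S) {
  counts <- 1
  for (k in 2:n) counts <- .convolve_ones(counts, k)
  # counts[i] = number of permutations with (i-1) inversions, i = 1..n0+1
  # S = n0 - 2 * inversions
  n0 <- n * (n - 1) / 2
  Sv <- n0 - 2 * (seq_along(counts) - 1)
  pr <- counts / sum(counts)
  min(1, 2 * min(sum(pr[Sv <= S]), sum(pr[Sv >= S])))
}

.convolve_ones <- function(counts, k) {
  out <- numeric(length(counts) + k - 1L)
  for (j in 0:(k - 1L)) {
    idx <- seq_along(counts) + j
    out[idx] <- out[idx] + counts
  }
  out
}

# Exact null of S with ties: enumerate all n! permutations of y against the
# fixed x. The tie pattern of both variables is preserved, so the tau-b
# denominator is constant and the S null is the exact permutation null.
.kendall_exact_ties <- function(x, y, S) {
  n <- length(x)
  perms <- .permutations(n)
  dx <- sign(outer(x, x, "-"))
  up <- upper.tri(dx)
  dxu <- dx[up]
  S_all <- apply(perms, 1L, function(p) {
    dy <- sign(outer(y[p], y[p], "-"))
    sum(dxu * dy[up])
  })
  min(1, 2 * min(mean(S_all <= S), mean(S_all >= S)))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Normal approximation with the tie-corrected variance of S.
.kendall_approx <- function(x, y, S) {
  n <- length(x)
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_S <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_S <= 0) return(NA_real_)
  z <- S / sqrt(var_S)
  2 * stats::pnorm(-abs(z))
}
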