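#' Convert a day of the year to a circular angle
#'
#' Day d (1--365) maps to 2*pi*d/365 radians, reduced modulo 2*pi (so day 365
#' maps to 0). Day 366 in leap years is folded onto day 365.
#'
#' @param day Integer vector of days of the year.
#' @return Angles in radians, in `[0, 2*pi)`.
#' @export
day_to_angle <- function(day) {
  if (any(day < 1 | day > 366)) stop("day of year must be in 1..366")
  day <- pmin(day, 365)
  (2 * pi * day / 365) %% (2 * pi)
}

#' Split flowering records into circular samples per ecotype
#'
#' @param records Data frame with columns `ecotype` and `day_of_year`.
#' @return Named list of angle vectors (radians), one per ecotype.
#' @export
circular_samples <- function(records) {
  stopifnot(all(c("ecotype", "day_of_year") %in% names(records)))
  lapply(split(records$day_of_year, records$ecotype), day_to_angle)
}

#' Binary flowering-day occupancy set
#'
#' The set of days of the year (1--365) with at least one flowering
#' observation, pooled across years. Optional circular gap-filling bridges
#' runs of flowering days separated by at most `gap_fill` missing days
#' (including across the year boundary); the default 0 performs no filling.
#'
#' @param records Data frame with a `day_of_year` column, or an integer
#'   vector of days.
#' @param gap_fill Maximum length (days) of interior gaps to bridge.
#' @return Sorted integer vector of flowering days.
#' @export
occupancy_set <- function(records, gap_fill = 0) {
  days <- if (is.data.frame(records)) records$day_of_year else records
  if (length(days) == 0) stop("no flowering records")
  if (any(days < 1 | days > 366)) stop("day of year must be in 1..366")
  present <- logical(365)
  present[pmin(as.integer(days), 365L)] <- TRUE
  if (gap_fill > 0 && any(present) && !all(present)) {
    # rotate so position 1 is a flowering day; every absence run is then
    # circularly bounded by presence, so short runs are interior gaps
    start <- which(present)[1]
    idx <- ((seq_len(365) + start - 2) %% 365) + 1  # rotated day order
    r <- rle(present[idx])
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!r$values[j] && r$lengths[j] <= gap_fill) {
        present[idx[begins[j]:ends[j]]] <- TRUE
      }
    }
  }
  which(present)
}

#' Mardia-Watson-Wheeler test of circular homogeneity
#'
#' Non-parametric k-sample test of whether circular samples share a common
#' distribution. Pooled observations are ranked circularly; rank r becomes
#' the uniform score beta = 2*pi*r/N, and the statistic is
#' W = 2 * sum_j (C_j^2 + S_j^2) / n_j with C_j, S_j the cosine and sine sums
#' of group j's scores. Under the null W is asymptotically chi-squared with
#' 2(k-1) degrees of freedom. Ties (many observations on the same day) are
#' broken by a seeded random rank assignment, recorded in the result.
#'
#' @param samples Named list of at least two angle vectors (radians).
#' @param tie_seed Integer seed for random tie-breaking.
#' @return An object of class `mww_result`: list with `W`, `df`, `p_value`,
#'   `n_per_group`, `tie_seed`.
#' @export
mww_test <- function(samples, tie_seed = 1L) {
  if (length(samples) < 2) stop("need at least two samples")
  n <- lengths(samples)
  if (any(n == 0)) stop("empty sample")
  if (any(n < 10)) warning("group sizes below 10: chi-squared approximation may be poor")
  ang <- unlist(samples, use.names = FALSE)
  grp <- rep(seq_along(samples), n)
  N <- length(ang)
  rk <- with_seed(tie_seed, rank(ang, ties.method = "random"))
  beta <- 2 * pi * rk / N
  W <- 2 * sum(vapply(seq_along(samples), function(j) {
    b <- beta[grp == j]
    (sum(cos(b))^2 + sum(sin(b))^2) / n[j]
  }, numeric(1)))
  df <- 2 * (length(samples) - 1)
  structure(list(W = W, df = df,
                 p_value = stats::pchisq(W, df, lower.tail = FALSE),
                 n_per_group = n, tie_seed = tie_seed),
            class = "mww_result")
}

#' @export
print.mww_result <- function(x, ...) {
  cat(sprintf("Mardia-Watson-Wheeler: W = %.3f, df = %d, P = %.4g\n",
              x$W, x$df, x$p_value))
  invisible(x)
}

#' Pairwise Mardia-Watson-Wheeler tests with Bonferroni correction
#'
#' One test per unordered pair of groups; adjusted p-values are
#' `min(1, raw * n_pairs)`.
#'
#' @param samples Named list of angle vectors (radians), one per group.
#' @param correction Only `"bonferroni"` is supported.
#' @param tie_seed Integer seed for random tie-breaking, shared across pairs.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `W`,
#'   `df`, `p_raw`, `p_adj`, `n_a`, `n_b`.
#' @export
pairwise_mww <- function(samples, correction = "bonferroni", tie_seed = 1L) {
  correction <- match.arg(correction, "bonferroni")
  if (length(samples) < 2) stop("need at least two groups")
  nm <- names(samples) %||% as.character(seq_along(samples))
  pairs <- utils::combn(seq_along(samples), 2)
  rows <- apply(pairs, 2, function(ij) {
    res <- mww_test(samples[ij], tie_seed = tie_seed)
    data.frame(group_a = nm[ij[1]], group_b = nm[ij[2]], W = res$W,
               df = res$df, p_raw = res$p_value,
               n_a = res$n_per_group[1], n_b = res$n_per_group[2])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out[, c("group_a", "group_b", "W", "df", "p_raw", "p_adj", "n_a", "n_b")]
}
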