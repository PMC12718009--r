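#' Permutational MANOVA on Euclidean distances
#'
#' Distance-based one-factor permutational MANOVA: features are (by default)
#' z-scored, squared Euclidean distances partitioned into between- and
#' within-group sums of squares, and the pseudo-F statistic
#' `(SSB / (k - 1)) / (SSW / (N - k))` compared with its distribution under
#' seeded random permutation of the group labels. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so its smallest attainable
#' value is `1 / (n_perm + 1)`.
#'
#' @param features Numeric matrix or data frame of features (rows =
#'   samples).
#' @param groups Group label per row (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed for the permutations.
#' @param scale Z-score each feature first (default `TRUE`; features often
#'   mix units).
#' @return Object of class `permanova_result`: list with `pseudo_F`,
#'   `df_between`, `df_within`, `p_value`, `n_perm`, `seed`.
#' @export
permanova <- function(features, groups, n_perm = 999, seed = 1L, scale = TRUE) {
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("features must be finite (handle missing values first)")
  groups <- as.factor(groups)
  n <- nrow(x)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    x <- scale(x[, sds > 0, drop = FALSE])
  }
  d2 <- as.matrix(stats::dist(x))^2
  sst <- sum(d2) / (2 * n)
  ssw_for <- function(g) {
    sum(vapply(split(seq_len(n), g), function(idx) {
      sum(d2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
  }
  fstat <- function(g) {
    ssw <- ssw_for(g)
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- fstat(groups)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    fstat(groups[sample.int(n)])
  }, numeric(1)))
  structure(list(pseudo_F = f_obs, df_between = k - 1, df_within = n - k,
                 p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, df = %d/%d, P = %.4g (%d permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise permutational MANOVA with Bonferroni correction
#'
#' One [permanova()] per unordered pair of groups, on the corresponding
#' subset of rows; adjusted p-values are `min(1, raw * n_pairs)`.
#'
#' @inheritParams permanova
#' @param correction Only `"bonferroni"` is supported.
#' @return Data frame with `group_a`, `group_b`, `pseudo_F`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_permanova <- function(features, groups, n_perm = 999, seed = 1L,
                               scale = TRUE, correction = "bonferroni") {
  match.arg(correction, "bonferroni")
  x <- as.matrix(features)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  pairs <- utils::combn(levels(groups), 2)
  rows <- apply(pairs, 2, function(ab) {
    sel <- groups %in% ab
    res <- permanova(x[sel, , drop = FALSE], droplevels(groups[sel]),
                     n_perm = n_perm, seed = seed, scale = scale)
    data.frame(group_a = ab[1], group_b = ab[2],
               pseudo_F = res$pseudo_F, p_raw = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out
}

#' PCA scores, loadings and explained variance
#'
#' Column-standardized principal component analysis via [stats::prcomp()].
#' Zero-variance columns are dropped with a warning.
#'
#' @param features Numeric matrix or data frame (rows = samples).
#' @param scale Standardize columns to unit variance (default `TRUE`).
#' @return List with `scores`, `loadings` (orthonormal columns),
#'   `explained_variance` (per component) and `prop_variance`.
#' @export
pca_scores <- function(features, scale = TRUE) {
  x <- as.matrix(features)
  if (ncol(x) < 2 || nrow(x) < 2) stop("need at least two features and two samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  list(scores = p$x, loadings = p$rotation,
       explained_variance = p$sdev^2,
       prop_variance = p$sdev^2 / sum(p$sdev^2))
}
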