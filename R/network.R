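#' Functional pollinator groups recognised by the package
#' @export
FUNCTIONAL_GROUPS <- c("solitary_bee", "carpenter_bee", "honey_bee",
                       "LTF", "MTF", "lycaenid")

#' Visitation rate
#'
#' Visits per flower per hour: `n_visits / (n_flowers * obs_hours)`.
#'
#' @param n_visits Number of visits observed.
#' @param n_flowers Number of flowers observed (> 0).
#' @param obs_hours Observation time in hours (> 0).
#' @return Visitation rate (visits per flower per hour).
#' @export
visitation_rate <- function(n_visits, n_flowers, obs_hours) {
  if (any(n_flowers <= 0)) stop("n_flowers must be positive")
  if (any(obs_hours <= 0)) stop("obs_hours must be positive")
  n_visits / (n_flowers * obs_hours)
}

#' Capped pollen load of a specimen
#'
#' Sums the head, thorax and abdomen conspecific pollen counts, capping each
#' body part at 1000 grains before summing (loads above 1000 grains per part
#' are not counted further).
#'
#' @param head,thorax,abdomen Pollen grain counts per body part.
#' @param cap Per-part cap (default 1000).
#' @return Total capped load per specimen.
#' @export
pollen_load <- function(head, thorax, abdomen, cap = 1000) {
  pmin(head, cap) + pmin(thorax, cap) + pmin(abdomen, cap)
}

#' Interaction matrices: visitation, pollen load and pollinator importance
#'
#' Builds site-by-functional-group (or ecotype-by-group) matrices of
#' visitation rate, mean conspecific pollen load and pollinator importance
#' (visitation rate x mean load). Pollen loads are per-part capped before
#' averaging over specimens; groups observed visiting but never caught get
#' load 0 and are flagged.
#'
#' @param visits Data frame with columns `site`, `ecotype`,
#'   `functional_group`, `n_visits`, `n_flowers`, `obs_hours`.
#' @param specimens Data frame with columns `site`, `functional_group`,
#'   `pollen_head`, `pollen_thorax`, `pollen_abdomen` and optionally
#'   `conspecific` (logical; non-conspecific records are excluded from
#'   loads).
#' @param level `"site"` or `"ecotype"`: the row dimension.
#' @param cap Per-part pollen cap.
#' @return List of matrices `rate`, `load`, `importance` (rows = sites or
#'   ecotypes, columns = functional groups) plus `no_specimens`, a data
#'   frame flagging cells with visits but no caught specimens.
#' @export
importance_matrix <- function(visits, specimens, level = c("site", "ecotype"),
                              cap = 1000) {
  level <- match.arg(level)
  rowvar <- visits[[level]]
  rows <- sort(unique(rowvar))
  cols <- sort(unique(c(visits$functional_group, specimens$functional_group)))
  agg <- stats::aggregate(cbind(n_visits, fl_hours = n_flowers * obs_hours) ~
                            row + functional_group,
                          data = data.frame(visits, row = rowvar), FUN = sum)
  rate <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  rate[cbind(agg$row, agg$functional_group)] <- agg$n_visits / agg$fl_hours
  if (!is.null(specimens$conspecific)) {
    specimens <- specimens[as.logical(specimens$conspecific), , drop = FALSE]
  }
  load <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(specimens)) {
    sprow <- if (level == "site") specimens$site else specimens$ecotype
    tot <- pollen_load(specimens$pollen_head, specimens$pollen_thorax,
                       specimens$pollen_abdomen, cap = cap)
    lagg <- stats::aggregate(tot ~ row + functional_group,
                             data = data.frame(row = sprow,
                                               functional_group = specimens$functional_group,
                                               tot = tot),
                             FUN = mean)
    lagg <- lagg[lagg$row %in% rows, , drop = FALSE]
    load[cbind(lagg$row, lagg$functional_group)] <- lagg$tot
  }
  flag <- which(rate > 0 & load == 0, arr.ind = TRUE)
  no_specimens <- data.frame(row = rows[flag[, 1]],
                             functional_group = cols[flag[, 2]])
  list(rate = rate, load = load, importance = rate * load,
       no_specimens = no_specimens)
}

#' Network-level specialization H2'
#'
#' Shannon-entropy specialization of a bipartite interaction matrix,
#' standardized between the minimum and maximum entropy achievable under the
#' observed marginal totals: H2' = (H2max - H2) / (H2max - H2min), clipped
#' to `[0, 1]`. 0 means interactions follow the marginals (no
#' specialization); 1 means maximal specialization.
#'
#' For an integer count web the entropy extremes respect the web's
#' granularity: H2max comes from integer proportional filling (floor of the
#' marginal-product expectation, greedy repair of the remaining units, then
#' margin-preserving 2x2 transfer hill-climbing) and H2min from randomized
#' multistart greedy concentration of whole units into as few cells as the
#' margins allow. For non-integer matrices the continuous limits are used
#' (the outer product of the marginals, and greedy concentration of
#' marginal mass); the continuous index is exactly invariant to rescaling
#' the matrix, and the integer index converges to it as the web total
#' grows.
#'
#' @param m Non-negative interaction matrix with a positive total.
#' @return H2' in `[0, 1]`.
#' @export
h2_prime <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("interaction matrix must be non-negative")
  if (sum(m) == 0) stop("all-zero interaction matrix")
  ent <- function(x) { x <- x[x > 0]; p <- x / sum(x); -sum(p * log(p)) }
  integral <- all(abs(m - round(m)) < 1e-9)
  if (integral && sum(m) <= 1e5) {
    M <- round(m)
    N <- sum(M)
    rs <- rowSums(M); cs <- colSums(M)
    # integer proportional filling for the maximum-entropy table
    E <- outer(rs, cs) / N
    a <- floor(E)
    # repair: place remaining units where the residual expectation is largest
    repeat {
      rd <- rs - rowSums(a); cd <- cs - colSums(a)
      if (sum(rd) == 0) break
      open <- outer(rd > 0, cd > 0, `&`)
      resid <- ifelse(open, E - a, -Inf)
      ij <- which(resid == max(resid), arr.ind = TRUE)[1, ]
      a[ij[1], ij[2]] <- a[ij[1], ij[2]] + 1
    }
    h2max <- ent(swap_optimize(a, maximize = TRUE))
    h2min <- min_entropy_greedy(rs, cs)
    h2 <- ent(M)
  } else {
    p <- m / sum(m)
    h2 <- ent(p)
    h2max <- ent(outer(rowSums(p), colSums(p)))
    h2min <- min_entropy_greedy(rowSums(p), colSums(p))
  }
  if (h2max - h2min < 1e-12) return(0)
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

# Hill-climb the entropy of an integer table over margin-preserving 2x2
# unit transfers (a[i1,j1]--, a[i2,j2]--, a[i1,j2]++, a[i2,j1]++), starting
# from a greedy solution. Small tables reach the constrained optimum.
swap_optimize <- function(a, maximize, max_iter = 2000) {
  ent1 <- function(x) { x <- x[x > 0]; p <- x / sum(x); -sum(p * log(p)) }
  sgn <- if (maximize) 1 else -1
  cur <- ent1(a)
  nr <- nrow(a); nc <- ncol(a)
  for (iter in seq_len(max_iter)) {
    best_gain <- 1e-12; best <- NULL
    for (i1 in seq_len(nr)) for (i2 in seq_len(nr)) {
      if (i1 == i2) next
      for (j1 in seq_len(nc)) for (j2 in seq_len(nc)) {
        if (j1 == j2 || a[i1, j1] == 0 || a[i2, j2] == 0) next
        deltas <- unique(c(1, min(a[i1, j1], a[i2, j2])))
        for (d in deltas) {
          b <- a
          b[i1, j1] <- b[i1, j1] - d; b[i2, j2] <- b[i2, j2] - d
          b[i1, j2] <- b[i1, j2] + d; b[i2, j1] <- b[i2, j1] + d
          gain <- sgn * (ent1(b) - cur)
          if (gain > best_gain) { best_gain <- gain; best <- b }
        }
      }
    }
    if (is.null(best)) break
    a <- best
    cur <- ent1(a)
  }
  a
}

# Minimum entropy under fixed margins by greedy concentration (repeatedly
# allocate min(row remainder, col remainder) to one cell), with randomized
# multistart over the pairing order: the deterministic largest-margins
# pairing is a good but not always optimal start. Internally seeded;
# leaves the caller's RNG state untouched.
min_entropy_greedy <- function(rs, cs, n_start = 60, tol = 1e-12) {
  ent1 <- function(x) { p <- x / sum(x); -sum(p * log(p)) }
  with_seed(20260924, {
    best <- Inf
    for (s in seq_len(n_start)) {
      rr <- rs; cc <- cs; cells <- numeric(0)
      while (sum(rr) > tol && sum(cc) > tol) {
        ri <- which(rr > tol); ci <- which(cc > tol)
        i <- if (s == 1 || length(ri) == 1) ri[which.max(rr[ri])] else
          sample(ri, 1, prob = rr[ri]^2)
        j <- if (s == 1 || length(ci) == 1) ci[which.max(cc[ci])] else
          sample(ci, 1, prob = cc[ci]^2)
        v <- min(rr[i], cc[j]); cells <- c(cells, v)
        rr[i] <- rr[i] - v; cc[j] <- cc[j] - v
      }
      best <- min(best, ent1(cells))
    }
    best
  })
}

#' Legitimate functional pollinator sets per ecotype
#'
#' An insect group counts as a legitimate pollinator of an ecotype if it was
#' recorded visiting (contacting the reproductive parts) or was caught
#' carrying conspecific pollen on head, thorax or abdomen. Sets are unions
#' over the ecotype's populations. An ecotype with no pollinator data gets
#' an empty set flagged `missing_data` (such ecotypes are excluded from the
#' pollinator barrier, not scored zero).
#'
#' @param visits Data frame with `ecotype`, `functional_group`, `n_visits`
#'   (rows with `n_visits > 0` count as visit evidence); may be `NULL`.
#' @param specimens Data frame with `ecotype`, `functional_group`,
#'   `pollen_head`, `pollen_thorax`, `pollen_abdomen`, optional
#'   `conspecific`; may be `NULL`.
#' @param ecotypes Optional character vector of ecotypes that must appear in
#'   the output even with no records.
#' @return Named list (one element per ecotype) of objects of class
#'   `functional_set`: list with `ecotype`, `groups` (character vector),
#'   `evidence` (data frame group/visit/pollen) and `missing_data` flag.
#' @export
functional_sets <- function(visits = NULL, specimens = NULL, ecotypes = NULL) {
  vis <- if (!is.null(visits) && nrow(visits)) {
    v <- visits[visits$n_visits > 0, c("ecotype", "functional_group")]
    unique(data.frame(v, evidence = "visit"))
  } else NULL
  pol <- if (!is.null(specimens) && nrow(specimens)) {
    sp <- specimens
    if (!is.null(sp$conspecific)) sp <- sp[as.logical(sp$conspecific), , drop = FALSE]
    has <- with(sp, pollen_head > 0 | pollen_thorax > 0 | pollen_abdomen > 0)
    sp <- sp[has, c("ecotype", "functional_group")]
    if (nrow(sp)) unique(data.frame(sp, evidence = "pollen")) else NULL
  } else NULL
  ev <- rbind(vis, pol)
  if (is.null(ev)) {
    ev <- data.frame(ecotype = character(), functional_group = character(),
                     evidence = character())
  }
  ecotypes <- ecotypes %||% sort(unique(ev$ecotype))
  out <- lapply(ecotypes, function(e) {
    sub <- ev[ev$ecotype == e, , drop = FALSE]
    groups <- sort(unique(sub$functional_group))
    structure(list(ecotype = e, groups = groups,
                   evidence = sub[, c("functional_group", "evidence")],
                   missing_data = length(groups) == 0),
              class = "functional_set")
  })
  names(out) <- ecotypes
  out
}

#' Importance-weighted pollinator trait per site
#'
#' Weighted mean of a pollinator trait (e.g. proboscis length) over the
#' functional groups visiting a site, weighted by pollinator importance:
#' `sum(importance * trait) / sum(importance)` over groups with trait data.
#'
#' @param importances Named numeric vector: importance per functional group.
#' @param traits Named numeric vector: trait value per functional group
#'   (`NA` allowed; such groups are excluded).
#' @return Weighted mean trait.
#' @export
weighted_trait <- function(importances, traits) {
  g <- intersect(names(importances), names(traits))
  w <- importances[g]; tr <- traits[g]
  ok <- !is.na(tr) & w > 0
  if (!any(ok)) stop("no functional group with positive importance and trait data")
  sum(w[ok] * tr[ok]) / sum(w[ok])
}

#' Ordinary least squares regression of a floral on a pollinator trait
#'
#' Thin wrapper around [stats::lm()] returning the quantities reported for
#' trait-matching analyses (slope, intercept, R-squared, overall F and its
#' p-value).
#'
#' @param x Explanatory variable (e.g. site-weighted proboscis length, mm).
#' @param y Response variable (e.g. floral tube length, mm).
#' @return List with `slope`, `intercept`, `r_squared`, `F`, `df`, `p_value`
#'   and the fitted `model`.
#' @export
ols_regress <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pv <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       F = if (is.null(fstat)) 0 else unname(fstat[1]),
       df = unname(fit$df.residual),
       p_value = unname(pv),
       model = fit)
}

#' Single most important pollinator per row of an importance matrix
#'
#' Row-wise argmax of the importance matrix ("pollinator niche" of a site or
#' ecotype). All-zero rows give `NA`; tied maxima are flagged, not silently
#' broken.
#'
#' @param importance Importance matrix (rows = sites/ecotypes).
#' @return Data frame with `row`, `top_group`, `importance`, `tied`.
#' @export
top_pollinator <- function(importance) {
  out <- lapply(rownames(importance), function(r) {
    v <- importance[r, ]
    if (all(v == 0)) {
      data.frame(row = r, top_group = NA_character_, importance = 0, tied = FALSE)
    } else {
      mx <- max(v)
      winners <- names(v)[v == mx]
      data.frame(row = r, top_group = winners[1], importance = mx,
                 tied = length(winners) > 1)
    }
  })
  do.call(rbind, out)
}
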