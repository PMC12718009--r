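#' Reproductive isolation from shared and unshared occurrence
#'
#' The barrier-strength equation for prezygotic barriers affecting
#' co-occurrence: RI = 1 - S / (S + U), where S is the shared and U the
#' unshared portion of occurrence. 0 means complete overlap (no barrier),
#' 1 no overlap (complete isolation).
#'
#' @param s Shared quantity (>= 0).
#' @param u Unshared quantity (>= 0).
#' @return RI in `[0, 1]`; `NA` with a warning when `s + u == 0`.
#' @export
ri_from_counts <- function(s, u) {
  if (any(s < 0) || any(u < 0)) stop("s and u must be non-negative")
  out <- 1 - s / (s + u)
  if (any(s + u == 0)) {
    warning("RI undefined for s + u = 0; returning NA")
    out[s + u == 0] <- NA_real_
  }
  out
}

barrier_estimate <- function(donor, recipient, barrier, s, u,
                             ci_low = NA_real_, ci_high = NA_real_,
                             n_boot = 0L, seed = NA_integer_,
                             ri = NULL) {
  data.frame(donor = donor, recipient = recipient, barrier = barrier,
             S = s, U = u,
             RI = ri %||% suppressWarnings(ri_from_counts(s, u)),
             ci_low = ci_low, ci_high = ci_high,
             n_boot = n_boot, seed = seed)
}

#' Directional ecogeographic isolation from binary ranges
#'
#' For gene flow from donor x into recipient y, S is the number of cells
#' where both predicted ranges are present and U is the recipient's unshared
#' presence cells. A recipient encased within the donor's range therefore
#' experiences no ecogeographic barrier to incoming gene flow (RI = 0),
#' while the reverse direction can be strongly isolated: the directionality
#' convention that reproduces the observed asymmetries between widespread
#' and encased ecotypes.
#'
#' @param donor_range,recipient_range Binary `env_grid` ranges on identical
#'   geometry.
#' @param donor,recipient Ecotype labels.
#' @return One-row data frame (barrier estimate): `donor`, `recipient`,
#'   `barrier`, `S`, `U`, `RI`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
ecogeographic_ri <- function(donor_range, recipient_range,
                             donor = "donor", recipient = "recipient") {
  ov <- overlap_summary(donor_range, recipient_range)
  if (ov$shared + ov$unshared_b == 0) stop("recipient range is empty")
  barrier_estimate(donor, recipient, "ecogeographic",
                   s = ov$shared, u = ov$unshared_b)
}

#' Directional phenological isolation from flowering-day sets
#'
#' S is the number of days of the year on which both ecotypes flower; U the
#' recipient's unshared flowering days (same directionality convention as
#' [ecogeographic_ri()]).
#'
#' @param days_donor,days_recipient Integer vectors of flowering days
#'   (1--365), e.g. from [occupancy_set()].
#' @param donor,recipient Ecotype labels.
#' @return One-row barrier-estimate data frame.
#' @export
phenological_ri <- function(days_donor, days_recipient,
                            donor = "donor", recipient = "recipient") {
  if (length(days_donor) == 0 || length(days_recipient) == 0) {
    stop("empty flowering-day set")
  }
  s <- length(intersect(days_donor, days_recipient))
  u <- length(setdiff(days_recipient, days_donor))
  barrier_estimate(donor, recipient, "phenological", s = s, u = u)
}

#' Directional pollinator-mediated isolation from functional pollinator sets
#'
#' Unweighted: S is the number of functional pollinator groups shared by
#' both ecotypes and U the number unique to the recipient. With `weights`
#' (a named per-group vector, e.g. record counts for the recipient), the
#' weights are summed instead of the counts. If either ecotype has no
#' pollinator data the estimate is missing (`RI = NA`) and is skipped - not
#' scored zero - when composing totals.
#'
#' @param set_donor,set_recipient `functional_set` objects (see
#'   [functional_sets()]) or plain character vectors of group names.
#' @param donor,recipient Ecotype labels.
#' @param weights Optional named numeric vector of per-group weights for the
#'   recipient's groups.
#' @return One-row barrier-estimate data frame (RI possibly `NA`).
#' @export
pollinator_ri <- function(set_donor, set_recipient,
                          donor = "donor", recipient = "recipient",
                          weights = NULL) {
  gset <- function(x) if (inherits(x, "functional_set")) x$groups else as.character(x)
  a <- gset(set_donor); b <- gset(set_recipient)
  if (length(a) == 0 || length(b) == 0) {
    return(barrier_estimate(donor, recipient, "pollinator",
                            s = NA_real_, u = NA_real_, ri = NA_real_))
  }
  shared <- intersect(a, b)
  unshared <- setdiff(b, a)
  if (is.null(weights)) {
    s <- length(shared); u <- length(unshared)
  } else {
    s <- sum(weights[shared], na.rm = TRUE)
    u <- sum(weights[unshared], na.rm = TRUE)
  }
  barrier_estimate(donor, recipient, "pollinator", s = s, u = u)
}

#' Sequential composition of barrier strengths into total premating RI
#'
#' Barriers act in sequence along the path to gene flow: barrier i removes
#' its fraction RI_i of the gene flow remaining after barriers 1..i-1, so
#' its absolute contribution is RI_i * prod(1 - RI_j, j < i) and the total
#' is their sum, equal to 1 - prod(1 - RI_i). The total is order-invariant;
#' the per-barrier contributions are not, and the conventional order
#' (ecogeographic, phenological, pollinator) is recorded. Missing components
#' (`NA`) are skipped, mirroring the treatment of ecotypes without
#' pollinator data.
#'
#' @param components Numeric vector of barrier strengths in `[0, 1]`
#'   (named, optionally; `NA` allowed).
#' @return List with `total_ri`, `absolute_contributions` (same order as the
#'   non-missing inputs), `components_used`.
#' @export
total_ri <- function(components) {
  used <- components[!is.na(components)]
  if (length(used) == 0) stop("no non-missing barrier components")
  if (any(used < 0 | used > 1)) stop("barrier components must lie in [0, 1]")
  before <- cumprod(c(1, utils::head(1 - used, -1)))
  contrib <- used * before
  list(total_ri = sum(contrib), absolute_contributions = contrib,
       components_used = used)
}

#' Percentile-bootstrap confidence interval for one barrier
#'
#' Resamples the raw observation units of each side with replacement,
#' re-runs the barrier estimator on every resample and reports the 2.5/97.5
#' percentiles. The units are barrier-specific: grid cells for the
#' ecogeographic barrier, flowering observation records for phenology,
#' per-population pollinator records for the pollinator barrier.
#'
#' @param raw_a,raw_b Vectors (or data frames, resampled by row) of raw
#'   units for the two sides.
#' @param estimator Function `(a, b) -> RI` applied to each pair of
#'   resamples.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer RNG seed (results are reproducible given the seed).
#' @return List with `ci_low`, `ci_high`, `boot` (the bootstrap
#'   distribution), `n_boot`, `seed`. Degenerate inputs (a single distinct
#'   unit on both sides) give a zero-width interval with a warning.
#' @export
bootstrap_ri <- function(raw_a, raw_b, estimator, n_boot = 10000, seed = 1L) {
  take <- function(x, idx) if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  n_a <- if (is.data.frame(raw_a)) nrow(raw_a) else length(raw_a)
  n_b <- if (is.data.frame(raw_b)) nrow(raw_b) else length(raw_b)
  if (n_a == 0 || n_b == 0) stop("empty raw data")
  distinct <- function(x) if (is.data.frame(x)) nrow(unique(x)) else length(unique(x))
  if (distinct(raw_a) == 1 && distinct(raw_b) == 1) {
    warning("single distinct unit: zero-width bootstrap interval")
  }
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    estimator(take(raw_a, sample.int(n_a, replace = TRUE)),
              take(raw_b, sample.int(n_b, replace = TRUE)))
  }, numeric(1)))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(ci_low = ci[1], ci_high = ci[2], boot = boot,
       n_boot = n_boot, seed = seed)
}

#' Confidence interval for total premating RI
#'
#' Draws one value per barrier per replicate (independently, with
#' replacement) from each component's bootstrap distribution, composes them
#' with [total_ri()] and reports the percentile interval.
#'
#' @param component_boots List of numeric bootstrap distributions, one per
#'   barrier.
#' @param n_boot Number of composition replicates.
#' @param seed Integer RNG seed.
#' @return List with `ci_low`, `ci_high`, `boot`.
#' @export
total_ri_ci <- function(component_boots, n_boot = 10000, seed = 1L) {
  if (length(component_boots) == 0) stop("no component distributions")
  draws <- with_seed(seed, sapply(component_boots, function(b) {
    sample(b, n_boot, replace = TRUE)
  }))
  draws <- matrix(draws, nrow = n_boot)
  tot <- 1 - apply(1 - draws, 1, prod)
  ci <- stats::quantile(tot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(ci_low = ci[1], ci_high = ci[2], boot = tot)
}

#' Legitimate pollinator records from visits and specimens
#'
#' One row per piece of evidence that a functional group legitimately
#' pollinates an ecotype (a visit contacting the reproductive parts, or a
#' caught specimen bearing conspecific pollen). These rows are the
#' resampling units of the pollinator bootstrap.
#'
#' @param visits,specimens As in [functional_sets()].
#' @return Data frame with `ecotype`, `site` (if available),
#'   `functional_group`, `evidence`.
#' @export
legitimate_records <- function(visits = NULL, specimens = NULL) {
  getcol <- function(d, nm) if (nm %in% names(d)) d[[nm]] else NA_character_
  vis <- if (!is.null(visits) && nrow(visits)) {
    v <- visits[visits$n_visits > 0, , drop = FALSE]
    data.frame(ecotype = v$ecotype, site = getcol(v, "site"),
               functional_group = v$functional_group, evidence = "visit")
  } else NULL
  pol <- if (!is.null(specimens) && nrow(specimens)) {
    sp <- specimens
    if (!is.null(sp$conspecific)) sp <- sp[as.logical(sp$conspecific), , drop = FALSE]
    has <- with(sp, pollen_head > 0 | pollen_thorax > 0 | pollen_abdomen > 0)
    sp <- sp[has, , drop = FALSE]
    if (nrow(sp)) data.frame(ecotype = sp$ecotype, site = getcol(sp, "site"),
                             functional_group = sp$functional_group,
                             evidence = "pollen") else NULL
  } else NULL
  out <- rbind(vis, pol)
  if (is.null(out)) {
    out <- data.frame(ecotype = character(), site = character(),
                      functional_group = character(), evidence = character())
  }
  out
}

#' Full directed table of premating barriers and totals
#'
#' Computes, for every ordered pair of ecotypes (n * (n - 1) directions),
#' the ecogeographic, phenological and pollinator barrier estimates, the
#' sequentially composed total premating RI, and (for `n_boot > 0`)
#' percentile-bootstrap confidence intervals. Directions involving an
#' ecotype without pollinator data compose the total from the remaining two
#' barriers and are flagged.
#'
#' Bootstrap resampling is done on the barrier-specific raw units (grid
#' cells / flowering records / pollinator records), drawn as multinomial
#' counts over the distinct units, which is distributionally identical to
#' resampling the unit list with replacement.
#'
#' @param ranges Named list of binary `env_grid` ranges, one per ecotype.
#' @param flowering Data frame with columns `ecotype`, `day_of_year`.
#' @param pollinator_records Data frame from [legitimate_records()] (or any
#'   data frame with `ecotype` and `functional_group`); may be `NULL` to
#'   skip the pollinator barrier entirely.
#' @param gap_fill Interior gap length bridged when building flowering-day
#'   occupancy (see [occupancy_set()]).
#' @param n_boot Bootstrap replicates per barrier (0 = no intervals).
#' @param seed Integer RNG seed for all bootstrap streams.
#' @return Data frame with one row per (direction, barrier) plus one
#'   `"total"` row per direction: columns `donor`, `recipient`, `barrier`,
#'   `S`, `U`, `RI`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `n_barriers_used`.
#' @export
ri_table <- function(ranges, flowering, pollinator_records = NULL,
                     gap_fill = 0, n_boot = 0, seed = 1L) {
  ecotypes <- names(ranges)
  stopifnot(length(ecotypes) >= 2)
  days <- lapply(ecotypes, function(e) {
    occupancy_set(flowering[flowering$ecotype == e, , drop = FALSE],
                  gap_fill = gap_fill)
  })
  names(days) <- ecotypes
  polgroups <- lapply(ecotypes, function(e) {
    if (is.null(pollinator_records)) character(0) else
      sort(unique(pollinator_records$functional_group[
        pollinator_records$ecotype == e]))
  })
  names(polgroups) <- ecotypes
  polcounts <- lapply(ecotypes, function(e) {
    if (is.null(pollinator_records)) integer(0) else
      table(pollinator_records$functional_group[pollinator_records$ecotype == e])
  })
  names(polcounts) <- ecotypes
  daycounts <- lapply(ecotypes, function(e) {
    table(pmin(flowering$day_of_year[flowering$ecotype == e], 365L))
  })
  names(daycounts) <- ecotypes

  boot_counts <- function(counts, n_boot) {
    # multinomial resample of unit labels; returns labels x n_boot matrix
    stats::rmultinom(n_boot, sum(counts), prob = counts / sum(counts))
  }

  rows <- list()
  for (x in ecotypes) for (y in setdiff(ecotypes, x)) {
    eco <- ecogeographic_ri(ranges[[x]], ranges[[y]], x, y)
    phe <- phenological_ri(days[[x]], days[[y]], x, y)
    pol <- pollinator_ri(polgroups[[x]], polgroups[[y]], x, y)
    boots <- list()
    if (n_boot > 0) {
      # ecogeographic: joint resample of valid cells via category counts
      va <- ranges[[x]]$values; vb <- ranges[[y]]$values
      ok <- !is.na(va) & !is.na(vb)
      cat4 <- c(n11 = sum(va[ok] == 1 & vb[ok] == 1),
                n01 = sum(va[ok] == 0 & vb[ok] == 1),
                n10 = sum(va[ok] == 1 & vb[ok] == 0),
                n00 = sum(va[ok] == 0 & vb[ok] == 0))
      eb <- with_seed(child_seed(seed, paste0("eco", x, y)), {
        cc <- boot_counts(cat4, n_boot)
        suppressWarnings(ri_from_counts(cc["n11", ], cc["n01", ]))
      })
      eco$ci_low <- stats::quantile(eb, 0.025, names = FALSE, na.rm = TRUE)
      eco$ci_high <- stats::quantile(eb, 0.975, names = FALSE, na.rm = TRUE)
      eco$n_boot <- n_boot; eco$seed <- seed
      boots$eco <- eb
      # phenological: resample flowering records per ecotype
      pb <- with_seed(child_seed(seed, paste0("phe", x, y)), {
        ca <- boot_counts(daycounts[[x]], n_boot)
        cb <- boot_counts(daycounts[[y]], n_boot)
        da <- as.integer(rownames(ca)); db <- as.integer(rownames(cb))
        vapply(seq_len(n_boot), function(i) {
          sa <- occupancy_set(da[ca[, i] > 0], gap_fill = gap_fill)
          sb <- occupancy_set(db[cb[, i] > 0], gap_fill = gap_fill)
          1 - length(intersect(sa, sb)) / length(sb)
        }, numeric(1))
      })
      phe$ci_low <- stats::quantile(pb, 0.025, names = FALSE)
      phe$ci_high <- stats::quantile(pb, 0.975, names = FALSE)
      phe$n_boot <- n_boot; phe$seed <- seed
      boots$phe <- pb
      # pollinator: resample legitimate records per ecotype
      if (!is.na(pol$RI)) {
        ob <- with_seed(child_seed(seed, paste0("pol", x, y)), {
          ca <- boot_counts(polcounts[[x]], n_boot)
          cb <- boot_counts(polcounts[[y]], n_boot)
          ga <- rownames(ca); gb <- rownames(cb)
          vapply(seq_len(n_boot), function(i) {
            sa <- ga[ca[, i] > 0]; sb <- gb[cb[, i] > 0]
            1 - length(intersect(sa, sb)) / length(sb)
          }, numeric(1))
        })
        pol$ci_low <- stats::quantile(ob, 0.025, names = FALSE)
        pol$ci_high <- stats::quantile(ob, 0.975, names = FALSE)
        pol$n_boot <- n_boot; pol$seed <- seed
        boots$pol <- ob
      }
    }
    comp <- c(ecogeographic = eco$RI, phenological = phe$RI,
              pollinator = pol$RI)
    tot <- total_ri(comp)
    trow <- barrier_estimate(x, y, "total",
                             s = NA_real_, u = NA_real_,
                             ri = tot$total_ri)
    if (n_boot > 0) {
      tci <- total_ri_ci(boots, n_boot = n_boot,
                         seed = child_seed(seed, paste0("tot", x, y)))
      trow$ci_low <- tci$ci_low; trow$ci_high <- tci$ci_high
      trow$n_boot <- n_boot; trow$seed <- seed
    }
    block <- rbind(eco, phe, pol, trow)
    block$n_barriers_used <- length(tot$components_used)
    rows[[paste(x, y, sep = "->")]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complex-wide mean barrier strengths
#'
#' Mean RI per barrier over all gene-flow directions with a non-missing
#' estimate, the headline summary of a directed RI table.
#'
#' @param table Output of [ri_table()].
#' @return Named numeric vector of mean RI per barrier (including
#'   `"total"`).
#' @export
ri_summary <- function(table) {
  tapply(table$RI, table$barrier, mean, na.rm = TRUE)
}
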