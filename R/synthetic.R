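#' Build a synthetic ecotype-complex scenario
#'
#' A scenario fixes the generative ground truth for a whole ecotype complex:
#' per ecotype a 2-D habitat-suitability surface (elliptical niche with a
#' logistic edge), a true flowering interval plus a von Mises observation
#' law, a set of functional pollinator groups with dominance probabilities,
#' sum-of-Gaussians floral reflectance templates and a morphological trait
#' distribution. Every barrier strength is exactly computable from the
#' scenario (see [true_ri()]), so estimator pipelines can be validated
#' end-to-end.
#'
#' The default preset has seven ecotypes qualitatively mirroring a
#' well-studied ecotype complex: two widespread lowland ecotypes, one
#' widespread long-flowering ecotype, a small ecotype encased (in range and
#' season) within the widespread ones and lacking pollinator data, plus
#' three geographically restricted ecotypes.
#'
#' @param config Optional named list overriding any top-level element of the
#'   preset (e.g. `grid`, `ecotypes`).
#' @return Object of class `ecotype_scenario`.
#' @export
build_scenario <- function(config = NULL) {
  eco <- function(centre, sigma, flower, pollinators, peak_nm, trait_mu) {
    list(niche = list(centre = centre, sigma = sigma, base = 0,
                      top = 0.98, edge_k = 8, tau = NA_real_),
         flowering = list(start = flower[1], end = flower[2], kappa = 1),
         pollinators = pollinators,
         spectra = list(tepal = list(centres = c(350, peak_nm),
                                     widths = c(25, 40),
                                     amps = c(15, 55), floor = 5)),
         morphology = list(mean = trait_mu,
                           sd = abs(trait_mu) * 0.08 + 0.2))
  }
  trait_names <- c("tube_length", "flower_gape", "petal_size",
                   "inflorescence_height", "leaf_length", "leaf_width")
  tm <- function(...) stats::setNames(c(...), trait_names)
  scenario <- list(
    grid = list(nrow = 60, ncol = 80, xll = 0, yll = 0, cellsize = 1),
    ecotypes = list(
      albidus = eco(c(18, 38), c(10, 8), c(213, 274),
                    c(solitary_bee = 0.6, carpenter_bee = 0.4), 480,
                    tm(25, 9, 32, 420, 300, 9)),
      blandus = eco(c(27, 27), c(5, 4), c(258, 299),
                    numeric(0), 560,
                    tm(33, 11, 36, 500, 380, 11)),
      callistus = eco(c(24, 30), c(11, 9), c(229, 289),
                      c(MTF = 0.4, LTF = 0.3, solitary_bee = 0.3), 600,
                      tm(30, 10, 30, 460, 350, 10)),
      high_altitude = eco(c(22, 52), c(7, 3.5), c(335, 31),
                          c(MTF = 0.4, LTF = 0.3, solitary_bee = 0.3), 520,
                          tm(28, 10, 28, 380, 260, 8)),
      langeberg = eco(c(62, 40), c(9, 3.5), c(289, 349),
                      c(solitary_bee = 0.5, honey_bee = 0.3, lycaenid = 0.2),
                      440, tm(22, 8, 26, 360, 280, 9)),
      macowanianus = eco(c(34, 22), c(13, 8), c(244, 370),
                         c(MTF = 0.4, LTF = 0.3, solitary_bee = 0.3), 640,
                         tm(34, 11, 37, 510, 390, 11)),
      prismatosiphon = eco(c(52, 12), c(5, 4), c(213, 268),
                           c(LTF = 0.55, solitary_bee = 0.45), 580,
                           tm(36, 10, 33, 440, 320, 10))
    ),
    pollination = list(n_flowers = 30, obs_hours = 3, dominant_rate = 0.25,
                       minor_rate_frac = 0.25, pollen_mu = 350,
                       pollen_size = 1.2),
    traits = list(proboscis_mm = c(solitary_bee = 9, carpenter_bee = 7,
                                   honey_bee = 6, LTF = 33, MTF = 10,
                                   lycaenid = 13),
                  thorax_depth_mm = c(solitary_bee = 4.5, carpenter_bee = 7,
                                      honey_bee = 4, LTF = 5, MTF = 4,
                                      lycaenid = 2.5))
  )
  for (nm in names(config)) scenario[[nm]] <- config[[nm]]
  scenario <- structure(scenario, class = "ecotype_scenario")
  # The true presence threshold of each ecotype is its population-level
  # equal sensitivity-specificity operating point (suitability-weighted
  # presence score distribution vs uniform background over the grid), the
  # quantity the thresholding estimator is consistent for. A tau supplied
  # via config is kept.
  for (e in names(scenario$ecotypes)) {
    if (is.na(scenario$ecotypes[[e]]$niche$tau)) {
      v <- as.vector(suitability_surface(scenario, e)$values)
      scenario$ecotypes[[e]]$niche$tau <- population_ess_threshold(v)
    }
  }
  ok <- vapply(scenario$ecotypes, function(e) {
    e$niche$tau > 0 && e$niche$tau < 1 &&
      all(c(e$flowering$start, e$flowering$end) %in% 1:370) &&
      (length(e$pollinators) == 0 ||
         abs(sum(e$pollinators) - 1) < 1e-8)
  }, logical(1))
  if (!all(ok)) stop("invalid ecotype parameters: ",
                     paste(names(ok)[!ok], collapse = ", "))
  scenario
}

# Population-level equal sensitivity-specificity threshold of a suitability
# surface: presence scores weighted by suitability mass, background uniform
# over cells. Same objective and tie rules as equal_ss_threshold().
population_ess_threshold <- function(v) {
  v <- v[!is.na(v)]
  cand <- sort(unique(v))
  w <- v / sum(v)
  ord <- order(v)
  cum_w <- cumsum(w[ord])          # presence mass with score < t upper bound
  cum_n <- seq_along(v) / length(v)
  sens <- spec <- numeric(length(cand))
  pos_lt <- vapply(cand, function(t) sum(v < t), numeric(1))
  for (i in seq_along(cand)) {
    lt <- pos_lt[i]
    sens[i] <- 1 - if (lt == 0) 0 else cum_w[lt]
    spec[i] <- if (lt == 0) 0 else cum_n[lt]
  }
  d <- abs(sens - spec)
  best <- which(d == min(d))
  if (length(best) > 1) {
    s <- (sens + spec)[best]
    best <- best[s == max(s)]
  }
  cand[best[1]]
}

#' @export
print.ecotype_scenario <- function(x, ...) {
  cat("ecotype_scenario:", length(x$ecotypes), "ecotypes on a",
      x$grid$nrow, "x", x$grid$ncol, "grid\n")
  invisible(x)
}

#' Serialize / parse a scenario (plain text)
#'
#' @param scenario An `ecotype_scenario`.
#' @param path File path.
#' @return `read_scenario()` an `ecotype_scenario`; `write_scenario()`
#'   invisibly the scenario.
#' @export
write_scenario <- function(scenario, path) {
  dput(unclass(scenario), file = path,
       control = c("digits17", "keepInteger", "keepNA", "niceNames"))
  invisible(scenario)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  structure(dget(path), class = "ecotype_scenario")
}

# Normalized elliptical distance of points from an ecotype's niche centre.
niche_u <- function(eco, x, y) {
  sqrt(((x - eco$niche$centre[1]) / eco$niche$sigma[1])^2 +
         ((y - eco$niche$centre[2]) / eco$niche$sigma[2])^2)
}

#' True habitat-suitability surface of one ecotype
#'
#' Suitability at a cell centre is `base + (top - base) * plogis(-k(u - 1))`
#' where u is the normalized elliptical distance from the niche centre: a
#' plateau of high suitability with a logistic edge of steepness k crossing
#' `(base + top) / 2` exactly at u = 1. With the default threshold tau = 0.5
#' the true binary range is exactly the u <= 1 ellipse.
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @return An `env_grid` of suitabilities in `[0, 1]`.
#' @export
suitability_surface <- function(scenario, ecotype) {
  g <- scenario$grid
  eco <- scenario$ecotypes[[ecotype]]
  cx <- g$xll + (seq_len(g$ncol) - 0.5) * g$cellsize
  cy <- g$yll + (g$nrow - seq_len(g$nrow) + 0.5) * g$cellsize
  u <- niche_u(eco, matrix(cx, g$nrow, g$ncol, byrow = TRUE),
               matrix(cy, g$nrow, g$ncol))
  s <- eco$niche$base + (eco$niche$top - eco$niche$base) *
    stats::plogis(-eco$niche$edge_k * (u - 1))
  env_grid(s, g$xll, g$yll, g$cellsize)
}

#' Days of the year covered by a (possibly wrapping) flowering interval
#'
#' @param start,end Interval bounds in days; `end` may exceed 365 or be
#'   smaller than `start`, both meaning a wrap across the year boundary.
#' @return Sorted integer vector of days in 1..365.
#' @export
interval_days <- function(start, end) {
  end <- ifelse(end > 365, end - 365, end)
  if (start <= end) start:end else sort(c(start:365, 1:end))
}

#' Sample occurrence points proportional to suitability
#'
#' Rejection sampling: uniform proposals over the grid extent accepted with
#' probability suitability / max(suitability); every accepted point lies
#' where suitability is positive. Accuracy and geoprivacy columns emulate
#' citizen-science metadata (all records pass the default quality filter).
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @param n Number of points (>= 1).
#' @param seed Integer RNG seed.
#' @return Data frame `ecotype, lon, lat, accuracy_m, geoprivacy`.
#' @export
sample_occurrences <- function(scenario, ecotype, n, seed = 1L) {
  stopifnot(n >= 1)
  g <- scenario$grid
  surf <- suitability_surface(scenario, ecotype)
  mx <- max(surf$values)
  if (mx <= 0) stop("all-zero suitability surface")
  eco <- scenario$ecotypes[[ecotype]]
  with_seed(child_seed(seed, paste0("occ", ecotype)), {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- (n - length(xs)) * 3 + 20
      px <- stats::runif(m, g$xll, g$xll + g$ncol * g$cellsize)
      py <- stats::runif(m, g$yll, g$yll + g$nrow * g$cellsize)
      u <- niche_u(eco, px, py)
      s <- eco$niche$base + (eco$niche$top - eco$niche$base) *
        stats::plogis(-eco$niche$edge_k * (u - 1))
      keep <- stats::runif(m) < s / mx & s > 0
      xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
    }
    data.frame(ecotype = ecotype, lon = xs[1:n], lat = ys[1:n],
               accuracy_m = round(stats::runif(n, 5, 95), 1),
               geoprivacy = "open")
  })
}

#' Sample flowering observation records
#'
#' Von Mises draws around the circular midpoint of the true flowering
#' interval, truncated to the interval and rounded to integer days. The
#' interval, not the von Mises law, is the ground truth of the phenological
#' barrier; the law only shapes observation density within the season.
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @param n Number of records (>= 1).
#' @param seed Integer RNG seed.
#' @return Data frame `ecotype, day_of_year, year`.
#' @export
sample_flowering <- function(scenario, ecotype, n, seed = 1L) {
  stopifnot(n >= 1)
  fl <- scenario$ecotypes[[ecotype]]$flowering
  days_ok <- interval_days(fl$start, fl$end)
  if (length(days_ok) == 0) stop("empty flowering interval")
  end <- ifelse(fl$end > 365, fl$end, ifelse(fl$end < fl$start, fl$end + 365, fl$end))
  mu <- 2 * pi * ((fl$start + end) / 2) / 365
  with_seed(child_seed(seed, paste0("flw", ecotype)), {
    out <- integer(0)
    while (length(out) < n) {
      m <- (n - length(out)) * 2 + 20
      th <- rvonmises(m, mu, fl$kappa)
      d <- round(th * 365 / (2 * pi))
      d[d == 0] <- 365L
      d <- d[d %in% days_ok]
      out <- c(out, d)
    }
    data.frame(ecotype = ecotype, day_of_year = out[1:n],
               year = sample(2020:2023, n, replace = TRUE))
  })
}

#' Sample pollinator observations and specimens
#'
#' Each population draws one dominant functional group from the ecotype's
#' dominance probabilities; the dominant group visits at the scenario's
#' dominant rate and every other group in the ecotype's true set at a fixed
#' fraction of it (minor visitors). Visit counts are Poisson
#' (rate x flowers x hours); caught specimens carry negative-binomial
#' conspecific pollen counts (occasionally exceeding the 1000-grain cap, so
#' the capping rule is exercised) and functional-group-typical trait values.
#' An ecotype with an empty pollinator set emits empty tables, emulating an
#' ecotype without pollinator data.
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @param n_populations Number of populations (>= 1).
#' @param seed Integer RNG seed.
#' @return List of data frames `visits` (`site, ecotype, functional_group,
#'   n_visits, n_flowers, obs_hours`) and `specimens` (`site, ecotype,
#'   functional_group, proboscis_mm, thorax_depth_mm, pollen_head,
#'   pollen_thorax, pollen_abdomen, conspecific`).
#' @export
sample_pollination <- function(scenario, ecotype, n_populations = 12, seed = 1L) {
  stopifnot(n_populations >= 1)
  probs <- scenario$ecotypes[[ecotype]]$pollinators
  pp <- scenario$pollination
  empty <- list(
    visits = data.frame(site = character(), ecotype = character(),
                        functional_group = character(), n_visits = integer(),
                        n_flowers = numeric(), obs_hours = numeric()),
    specimens = data.frame(site = character(), ecotype = character(),
                           functional_group = character(),
                           proboscis_mm = numeric(), thorax_depth_mm = numeric(),
                           pollen_head = numeric(), pollen_thorax = numeric(),
                           pollen_abdomen = numeric(), conspecific = logical()))
  if (length(probs) == 0) return(empty)
  with_seed(child_seed(seed, paste0("pol", ecotype)), {
    vrows <- list(); srows <- list()
    for (p in seq_len(n_populations)) {
      site <- sprintf("%s_%02d", ecotype, p)
      dominant <- sample(names(probs), 1, prob = probs)
      for (grp in names(probs)) {
        rate <- pp$dominant_rate *
          if (grp == dominant) 1 else pp$minor_rate_frac
        nv <- stats::rpois(1, rate * pp$n_flowers * pp$obs_hours)
        vrows[[length(vrows) + 1L]] <- data.frame(
          site = site, ecotype = ecotype, functional_group = grp,
          n_visits = nv, n_flowers = pp$n_flowers, obs_hours = pp$obs_hours)
        if (nv > 0) {
          ns <- 1 + stats::rpois(1, min(nv, 4) / 2)
          pol <- matrix(stats::rnbinom(3 * ns, mu = pp$pollen_mu,
                                       size = pp$pollen_size), ncol = 3)
          srows[[length(srows) + 1L]] <- data.frame(
            site = site, ecotype = ecotype, functional_group = grp,
            proboscis_mm = pmax(1, stats::rnorm(
              ns, scenario$traits$proboscis_mm[grp], 1)),
            thorax_depth_mm = pmax(0.5, stats::rnorm(
              ns, scenario$traits$thorax_depth_mm[grp], 0.4)),
            pollen_head = pol[, 1], pollen_thorax = pol[, 2],
            pollen_abdomen = pol[, 3], conspecific = TRUE)
        }
      }
    }
    list(visits = do.call(rbind, vrows),
         specimens = if (length(srows)) do.call(rbind, srows) else empty$specimens)
  })
}

#' Sample reflectance spectra from an ecotype's template
#'
#' Template: a floor plus Gaussian peaks (percent reflectance), clipped to
#' `[0, 100]`. Noise: an independent smooth random curve per measurement
#' (Gaussian deviates smoothed over ~15 nm) scaled by `noise_sd`, which can
#' push values slightly below zero so the negative-value correction is
#' exercised.
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @param part Flower part with a template (default `"tepal"`).
#' @param n Number of measurements.
#' @param seed Integer RNG seed.
#' @param noise_sd Noise amplitude (percent reflectance; 0 gives the exact
#'   template).
#' @param grid Wavelength grid.
#' @return A `spectrum_set`.
#' @export
sample_spectra <- function(scenario, ecotype, part = "tepal", n = 5, seed = 1L,
                           noise_sd = 2, grid = 300:700) {
  tpl <- scenario$ecotypes[[ecotype]]$spectra[[part]]
  if (is.null(tpl)) stop("no spectral template for part '", part, "'")
  base <- tpl$floor + Reduce(`+`, lapply(seq_along(tpl$centres), function(i) {
    tpl$amps[i] * exp(-((grid - tpl$centres[i]) / tpl$widths[i])^2 / 2)
  }))
  base <- pmin(pmax(base, 0), 100)
  refl <- with_seed(child_seed(seed, paste0("spc", ecotype, part)), {
    sapply(seq_len(n), function(i) {
      if (noise_sd == 0) return(base)
      z <- stats::rnorm(length(grid))
      sm <- stats::filter(z, rep(1 / 15, 15), circular = TRUE)
      pmin(base + noise_sd * as.numeric(sm) * sqrt(15), 100)
    })
  })
  ids <- sprintf("%s_%s_%02d", ecotype, part, seq_len(n))
  colnames(refl) <- ids
  spectrum_set(grid, refl,
               data.frame(id = ids, ecotype = ecotype,
                          population = paste0(ecotype, "_01"),
                          flower_part = part),
               grid = grid)
}

#' Sample morphological trait measurements
#'
#' Independent Gaussian traits around the ecotype's mean vector.
#'
#' @param scenario An `ecotype_scenario`.
#' @param ecotype Ecotype name.
#' @param n Number of individuals.
#' @param seed Integer RNG seed.
#' @return Data frame with `ecotype`, `site` and one column per trait.
#' @export
sample_morphology <- function(scenario, ecotype, n, seed = 1L) {
  mo <- scenario$ecotypes[[ecotype]]$morphology
  with_seed(child_seed(seed, paste0("mor", ecotype)), {
    m <- sapply(names(mo$mean), function(tr) {
      stats::rnorm(n, mo$mean[tr], mo$sd[tr])
    })
    cbind(data.frame(ecotype = ecotype, site = paste0(ecotype, "_01")),
          as.data.frame(matrix(m, nrow = n,
                               dimnames = list(NULL, names(mo$mean)))))
  })
}

#' Ground-truth directed RI table of a scenario
#'
#' Exact shared/unshared quantities from the true threshold ranges, true
#' flowering intervals and true pollinator sets, under the
#' recipient-unshared directionality convention, composed with [total_ri()].
#' This is the oracle against which estimator pipelines are validated.
#'
#' @param scenario An `ecotype_scenario`.
#' @return A directed barrier table as from [ri_table()] (no intervals).
#' @export
true_ri <- function(scenario) {
  eco_names <- names(scenario$ecotypes)
  ranges <- lapply(eco_names, function(e) {
    binarize(suitability_surface(scenario, e),
             scenario$ecotypes[[e]]$niche$tau)
  })
  names(ranges) <- eco_names
  flowering <- do.call(rbind, lapply(eco_names, function(e) {
    fl <- scenario$ecotypes[[e]]$flowering
    data.frame(ecotype = e, day_of_year = interval_days(fl$start, fl$end))
  }))
  pol <- do.call(rbind, lapply(eco_names, function(e) {
    grp <- names(scenario$ecotypes[[e]]$pollinators)
    if (length(grp) == 0) return(NULL)
    data.frame(ecotype = e, functional_group = grp)
  }))
  ri_table(ranges, flowering, pol, gap_fill = 0, n_boot = 0)
}

#' Generate a complete synthetic dataset
#'
#' Draws every input class the estimation pipeline consumes (occurrences,
#' flowering records, pollinator tables, spectra, morphology) from one
#' scenario under one master seed (per-ecotype, per-class child streams keep
#' the draws independent).
#'
#' @param scenario An `ecotype_scenario`.
#' @param n_occurrences,n_flowering Records per ecotype.
#' @param n_populations Pollinator populations per ecotype.
#' @param n_spectra Spectra per ecotype (tepal).
#' @param n_morphology Individuals per ecotype.
#' @param seed Master integer seed.
#' @return List: `occurrences`, `flowering`, `visits`, `specimens`,
#'   `spectra` (list per ecotype), `morphology`, `surfaces` (list of
#'   `env_grid`), `scenario`, `seed`.
#' @export
simulate_dataset <- function(scenario, n_occurrences = 500, n_flowering = 500,
                             n_populations = 12, n_spectra = 5,
                             n_morphology = 20, seed = 1L) {
  eco_names <- names(scenario$ecotypes)
  occ <- do.call(rbind, lapply(eco_names, sample_occurrences,
                               scenario = scenario, n = n_occurrences,
                               seed = seed))
  flw <- do.call(rbind, lapply(eco_names, sample_flowering,
                               scenario = scenario, n = n_flowering,
                               seed = seed))
  pol <- lapply(eco_names, sample_pollination, scenario = scenario,
                n_populations = n_populations, seed = seed)
  spectra <- lapply(eco_names, sample_spectra, scenario = scenario,
                    n = n_spectra, seed = seed)
  names(spectra) <- eco_names
  morph <- do.call(rbind, lapply(eco_names, sample_morphology,
                                 scenario = scenario, n = n_morphology,
                                 seed = seed))
  surfaces <- lapply(eco_names, suitability_surface, scenario = scenario)
  names(surfaces) <- eco_names
  list(occurrences = occ, flowering = flw,
       visits = do.call(rbind, lapply(pol, `[[`, "visits")),
       specimens = do.call(rbind, lapply(pol, `[[`, "specimens")),
       spectra = spectra, morphology = morph, surfaces = surfaces,
       scenario = scenario, seed = seed)
}

#' Write a synthetic dataset in the external exchange formats
#'
#' occurrences.csv, flowering.csv, visits.csv, specimens.csv,
#' morphology.csv, spectra/<ecotype>.csv (+ metadata), grids/<ecotype>.asc
#' and truth_ri.csv under `dir`.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "grids"), showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  w(dataset$occurrences, "occurrences.csv")
  w(dataset$flowering, "flowering.csv")
  w(dataset$visits, "visits.csv")
  w(dataset$specimens, "specimens.csv")
  w(dataset$morphology, "morphology.csv")
  for (e in names(dataset$spectra)) {
    write_spectra(dataset$spectra[[e]],
                  file.path(dir, "spectra", paste0(e, ".csv")),
                  file.path(dir, "spectra", paste0(e, "_metadata.csv")))
  }
  for (e in names(dataset$surfaces)) {
    write_ascii_grid(dataset$surfaces[[e]],
                     file.path(dir, "grids", paste0(e, ".asc")))
  }
  w(true_ri(dataset$scenario), "truth_ri.csv")
  invisible(dir)
}

#' Estimate the directed RI table from synthetic (or real-format) data
#'
#' The full estimation pipeline: per ecotype, the suitability surface is
#' thresholded at the equal sensitivity-specificity threshold estimated from
#' suitability scores at the occurrence points versus uniform background
#' points; flowering-day occupancy is built from the records with interior
#' gap-filling; pollinator sets come from the legitimate visit/specimen
#' records. The three barriers and their sequential totals are then
#' assembled with [ri_table()].
#'
#' @param dataset Output of [simulate_dataset()] (or a list with the same
#'   elements built from real data files).
#' @param gap_fill Interior gap length (days) bridged in the occupancy sets
#'   (default 3: bridges short observation gaps within a season).
#' @param n_background Uniform background points per ecotype for threshold
#'   estimation (default 10000, the conventional background size for
#'   presence-background niche models).
#' @param n_boot,seed Passed to [ri_table()].
#' @return List: `table` (the directed barrier table), `thresholds`,
#'   `ranges`, `auc` (per-ecotype score AUC).
#' @export
estimate_ri_table <- function(dataset, gap_fill = 3, n_background = 10000,
                              n_boot = 0, seed = 1L) {
  sc <- dataset$scenario
  eco_names <- names(dataset$surfaces)
  g <- dataset$surfaces[[1]]
  nr <- nrow(g$values); nc <- ncol(g$values)
  thresholds <- numeric(0); ranges <- list(); auc <- numeric(0)
  for (e in eco_names) {
    pts <- dataset$occurrences[dataset$occurrences$ecotype == e, , drop = FALSE]
    pts <- filter_occurrences(pts)
    pres <- extract_env(pts, dataset$surfaces[e])[[e]]
    nb <- n_background
    bg <- with_seed(child_seed(seed, paste0("bg", e)), {
      data.frame(lon = stats::runif(nb, g$xll, g$xll + nc * g$cellsize),
                 lat = stats::runif(nb, g$yll, g$yll + nr * g$cellsize))
    })
    bgs <- extract_env(bg, dataset$surfaces[e])[[e]]
    t_hat <- equal_ss_threshold(pres, bgs)
    thresholds[e] <- t_hat
    auc[e] <- auc_score(pres, bgs)
    ranges[[e]] <- binarize(dataset$surfaces[[e]], t_hat)
  }
  recs <- legitimate_records(dataset$visits, dataset$specimens)
  tab <- ri_table(ranges, dataset$flowering,
                  if (nrow(recs)) recs else NULL,
                  gap_fill = gap_fill, n_boot = n_boot, seed = seed)
  list(table = tab, thresholds = thresholds, ranges = ranges, auc = auc)
}
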