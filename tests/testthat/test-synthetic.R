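test_that("the default scenario has seven ecotypes and is byte-stable", {
  sc1 <- build_scenario()
  sc2 <- build_scenario()
  expect_length(sc1$ecotypes, 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_scenario(sc1, f1); write_scenario(sc2, f2)
  expect_identical(readLines(f1), readLines(f2))
  sc3 <- read_scenario(f1)
  expect_equal(unclass(sc3), unclass(sc1))
  # one ecotype deliberately lacks pollinator data
  n_missing <- sum(vapply(sc1$ecotypes,
                          function(e) length(e$pollinators) == 0, logical(1)))
  expect_equal(n_missing, 1)
  expect_error(build_scenario(list(ecotypes = list(
    bad = modifyList(sc1$ecotypes[[1]],
                     list(niche = modifyList(sc1$ecotypes[[1]]$niche,
                                             list(tau = 2))))))),
    "invalid")
})

test_that("occurrence sampling follows the suitability surface", {
  sc <- build_scenario()
  o1 <- sample_occurrences(sc, "callistus", 200, seed = 9)
  o2 <- sample_occurrences(sc, "callistus", 200, seed = 9)
  expect_identical(o1, o2)
  # every point lies where suitability is positive (and overwhelmingly
  # within the true range, since suitability vanishes outside)
  surf <- suitability_surface(sc, "callistus")
  s_at <- extract_env(o1, list(s = surf))$s
  expect_true(all(s_at > 0))
  # empirical cell frequencies proportional to suitability (chi-squared GOF)
  o <- sample_occurrences(sc, "macowanianus", 5000, seed = 10)
  sm <- suitability_surface(sc, "macowanianus")
  col <- floor(o$lon) + 1; row <- nrow(sm$values) - floor(o$lat)
  cell <- (col - 1) * nrow(sm$values) + row
  keep_cells <- which(as.vector(sm$values) > 0.05)
  counts <- tabulate(match(cell, keep_cells), nbins = length(keep_cells))
  inside <- cell %in% keep_cells
  p_exp <- as.vector(sm$values)[keep_cells]
  p_exp <- p_exp / sum(p_exp)
  gof <- suppressWarnings(chisq.test(counts, p = p_exp))  # small expected counts in edge cells
  expect_gt(gof$p.value, 0.01)
  expect_gt(mean(inside), 0.97)
})

test_that("flowering samples stay inside the true interval with the right centre", {
  sc <- build_scenario()
  fl <- sc$ecotypes$macowanianus$flowering
  days_ok <- interval_days(fl$start, fl$end)
  f <- sample_flowering(sc, "macowanianus", 2000, seed = 11)
  expect_true(all(f$day_of_year %in% days_ok))
  expect_identical(f, sample_flowering(sc, "macowanianus", 2000, seed = 11))
  # kappa -> infinity concentrates all records on the central day
  sck <- build_scenario()
  sck$ecotypes$albidus$flowering$kappa <- 1e7
  fk <- sample_flowering(sck, "albidus", 50, seed = 12)
  mid <- round((sck$ecotypes$albidus$flowering$start +
                  sck$ecotypes$albidus$flowering$end) / 2)
  expect_true(all(abs(fk$day_of_year - mid) <= 1))
  # circular mean of many draws sits within 2 days of the centre at kappa 4
  sck$ecotypes$albidus$flowering$kappa <- 4
  fm <- sample_flowering(sck, "albidus", 10000, seed = 13)
  ang <- day_to_angle(fm$day_of_year)
  mu_hat <- atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)
  mu_day <- mu_hat * 365 / (2 * pi)
  expect_lt(min(abs(mu_day - mid), 365 - abs(mu_day - mid)), 2)
})

test_that("pollination sampling respects rates, dominance and missing-data ecotypes", {
  sc <- build_scenario()
  # the no-pollinator ecotype emits empty tables
  bl <- sample_pollination(sc, "blandus", 10, seed = 14)
  expect_equal(nrow(bl$visits), 0)
  expect_equal(nrow(bl$specimens), 0)
  p <- sample_pollination(sc, "callistus", 50, seed = 15)
  expect_identical(p, sample_pollination(sc, "callistus", 50, seed = 15))
  # dominant-group visit counts have the Poisson mean rate*flowers*hours
  lam <- sc$pollination$dominant_rate * sc$pollination$n_flowers *
    sc$pollination$obs_hours
  dom <- do.call(rbind, lapply(split(p$visits, p$visits$site), function(v) {
    v[which.max(v$n_visits), ]
  }))
  expect_equal(mean(dom$n_visits), lam, tolerance = 0.1)
  # zero rate yields zero visits
  sc0 <- build_scenario()
  sc0$pollination$dominant_rate <- 0
  v0 <- sample_pollination(sc0, "callistus", 5, seed = 16)
  expect_true(all(v0$visits$n_visits == 0))
  # specimens only for groups with visits; all conspecific here
  expect_true(all(p$specimens$functional_group %in% p$visits$functional_group))
})

test_that("spectral templates are recovered at zero noise and bounded always", {
  sc <- build_scenario()
  s0 <- sample_spectra(sc, "langeberg", n = 2, seed = 17, noise_sd = 0)
  expect_equal(s0$reflectance[, 1], s0$reflectance[, 2])
  tpl <- sc$ecotypes$langeberg$spectra$tepal
  peak_wl <- s0$wavelengths[which.max(s0$reflectance[, 1])]
  expect_lt(abs(peak_wl - tpl$centres[which.max(tpl$amps)]), 3)
  s1 <- sample_spectra(sc, "langeberg", n = 6, seed = 18, noise_sd = 3)
  expect_true(all(s1$reflectance <= 100))
  # sampled hexagon centroids recover the template-designed separation
  bee <- bee_receptor_system()
  tpl_loci <- lapply(c("albidus", "macowanianus"), function(e) {
    tp <- colour_loci(sample_spectra(sc, e, n = 1, seed = 1, noise_sd = 0), bee)
    c(tp$x, tp$y)
  })
  d_tpl <- sqrt(sum((tpl_loci[[1]] - tpl_loci[[2]])^2))
  cents <- lapply(c("albidus", "macowanianus"), function(e) {
    l <- colour_loci(sample_spectra(sc, e, n = 20, seed = 19, noise_sd = 2), bee)
    c(mean(l$x), mean(l$y))
  })
  d_hat <- sqrt(sum((cents[[1]] - cents[[2]])^2))
  expect_lt(abs(d_hat - d_tpl) / d_tpl, 0.1)
})

test_that("ground-truth RI is exact set arithmetic on the scenario", {
  sc <- build_scenario()
  truth <- true_ri(sc)
  expect_equal(nrow(truth), 42 * 4)
  # two identically parameterized ecotypes: every barrier zero
  sc2 <- build_scenario()
  sc2$ecotypes <- sc2$ecotypes[c("callistus", "macowanianus")]
  sc2$ecotypes$macowanianus <- sc2$ecotypes$callistus
  t2 <- true_ri(sc2)
  expect_true(all(t2$RI == 0))
  # fully disjoint ranges, seasons and pollinators: every barrier one
  sc3 <- build_scenario()
  sc3$ecotypes <- sc3$ecotypes[c("albidus", "langeberg")]
  sc3$ecotypes$albidus$niche$centre <- c(15, 15)
  sc3$ecotypes$albidus$niche$sigma <- c(4, 4)
  sc3$ecotypes$langeberg$niche$centre <- c(65, 45)
  sc3$ecotypes$langeberg$niche$sigma <- c(4, 4)
  sc3$ecotypes$albidus$flowering[c("start", "end")] <- list(50, 100)
  sc3$ecotypes$langeberg$flowering[c("start", "end")] <- list(200, 250)
  sc3$ecotypes$albidus$pollinators <- c(carpenter_bee = 1)
  sc3$ecotypes$langeberg$pollinators <- c(lycaenid = 1)
  t3 <- true_ri(sc3)
  expect_true(all(t3$RI == 1))
})

test_that("synthetic datasets round-trip through the package readers", {
  sc <- build_scenario()
  ds <- simulate_dataset(sc, n_occurrences = 40, n_flowering = 40,
                         n_populations = 3, n_spectra = 2, n_morphology = 5,
                         seed = 20)
  dir <- tempfile()
  expect_no_warning(write_synthetic_dataset(ds, dir))
  occ <- read.csv(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(ds$occurrences))
  g <- expect_no_warning(read_ascii_grid(file.path(dir, "grids", "callistus.asc")))
  expect_equal(dim(g$values), dim(ds$surfaces$callistus$values))
  expect_equal(g$values, round(ds$surfaces$callistus$values, 10),
               tolerance = 1e-6)
  sp <- expect_no_warning(
    read_spectra(file.path(dir, "spectra", "albidus.csv"),
                 file.path(dir, "spectra", "albidus_metadata.csv")))
  expect_equal(ncol(sp$reflectance), 2)
  # end-to-end determinism: same master seed, same bytes
  ds2 <- simulate_dataset(sc, n_occurrences = 40, n_flowering = 40,
                          n_populations = 3, n_spectra = 2, n_morphology = 5,
                          seed = 20)
  dir2 <- tempfile()
  write_synthetic_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir, "occurrences.csv")),
                   readLines(file.path(dir2, "occurrences.csv")))
  expect_identical(readLines(file.path(dir, "visits.csv")),
                   readLines(file.path(dir2, "visits.csv")))
})

test_that("morphology samples separate ecotypes under permanova", {
  sc <- build_scenario()
  m <- rbind(sample_morphology(sc, "albidus", 15, seed = 21),
             sample_morphology(sc, "macowanianus", 15, seed = 21))
  res <- permanova(m[, -(1:2)], m$ecotype, n_perm = 199, seed = 1)
  expect_lt(res$p_value, 0.01)
})
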