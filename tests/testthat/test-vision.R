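test_that("von Kries normalization maps the background to unit catch and the origin", {
  for (kind in c("hexagon", "coc")) {
    r <- gaussian_system(kind)
    P <- quantum_catch(r$background, r)
    expect_equal(unname(P), rep(1, length(P)), tolerance = 1e-12)
    # linearity: doubling the stimulus doubles every catch
    expect_equal(unname(quantum_catch(2 * r$background, r)),
                 rep(2, length(P)), tolerance = 1e-12)
    E <- excitation(P)
    loc <- if (kind == "hexagon") {
      hexagon_locus(E[["UV"]], E[["B"]], E[["G"]])
    } else {
      coc_locus(E[["R7p"]], E[["R8p"]], E[["R7y"]], E[["R8y"]])
    }
    expect_equal(c(loc$x, loc$y), c(0, 0), tolerance = 1e-12)
  }
})

test_that("1 nm trapezoid quantum catch matches a 0.1 nm oracle within 0.5 %", {
  wl <- 300:700
  s_fun <- function(l) exp(-((l - 450) / 30)^2 / 2)
  r <- receptor_system(cbind(UV = s_fun(wl),
                             B = exp(-((wl - 500) / 25)^2 / 2),
                             G = exp(-((wl - 560) / 35)^2 / 2)),
                       illuminant = rep(1, length(wl)),
                       background = rep(25, length(wl)), "hexagon", wl)
  P <- quantum_catch(rep(50, length(wl)), r, "UV")
  expect_equal(unname(P), 2, tolerance = 1e-9)  # flat 50 % vs flat 25 %
  oracle <- qc_oracle(s_fun, function(l) rep(50, length(l)),
                      function(l) rep(1, length(l)),
                      function(l) rep(25, length(l)))
  expect_lt(abs(P - oracle) / oracle, 0.005)
  # a structured (sloping) stimulus against the same oracle
  refl <- function(l) 20 + 60 * (l - 300) / 400
  P2 <- quantum_catch(refl(wl), r, "UV")
  o2 <- qc_oracle(s_fun, refl, function(l) rep(1, length(l)),
                  function(l) rep(25, length(l)))
  expect_lt(abs(P2 - o2) / o2, 0.005)
  expect_error(quantum_catch(rep(1, length(wl)), r, "X"), "receptor")
  r0 <- receptor_system(r$sensitivities, rep(1, length(wl)),
                        rep(0, length(wl)), "hexagon", wl)
  expect_error(quantum_catch(rep(1, length(wl)), r0, "UV"), "zero")
})

test_that("hyperbolic excitation has the stated fixed points and saturation", {
  expect_equal(excitation(0), 0)
  expect_equal(excitation(1), 0.5)
  expect_equal(excitation(3), 0.75)
  expect_error(excitation(-0.1), "non-negative")
  p <- sort(runif(50, 0, 100))
  e <- excitation(p)
  expect_true(all(diff(e) > 0))        # monotone
  expect_true(all(e >= 0 & e < 1))
  expect_gt(excitation(1e6), 0.999999) # saturates towards 1
})

test_that("hexagon coordinates follow the colour-hexagon construction", {
  bg <- hexagon_locus(0.5, 0.5, 0.5)
  expect_equal(c(bg$x, bg$y), c(0, 0))
  blue <- hexagon_locus(0, 1, 0)
  expect_equal(c(blue$x, blue$y), c(0, 1))
  green <- hexagon_locus(0, 0, 1)
  expect_equal(c(green$x, green$y), c(sin(pi / 3), -0.5), tolerance = 1e-4)
  expect_error(hexagon_locus(1.2, 0, 0), "excitations")
  # loci for excitations in [0,1] stay within unit distance of the origin
  set.seed(21)
  for (i in 1:200) {
    e <- runif(3)
    l <- hexagon_locus(e[1], e[2], e[3])
    expect_lte(sqrt(l$x^2 + l$y^2), 1 + 1e-12)
  }
})

test_that("fly opponent coordinates and quadrant categories are assigned correctly", {
  l0 <- coc_locus(0.3, 0.3, 0.6, 0.6)
  expect_equal(c(l0$x, l0$y), c(0, 0))
  expect_equal(l0$quadrant, "origin/axis")
  q1 <- coc_locus(0.7, 0.2, 0.8, 0.1)
  expect_equal(q1$quadrant, "I")
  expect_equal(c(q1$x, q1$y), c(0.5, 0.7))
  expect_equal(coc_locus(0.1, 0.7, 0.8, 0.2)$quadrant, "II")
  expect_equal(coc_locus(0.1, 0.7, 0.2, 0.8)$quadrant, "III")
  expect_equal(coc_locus(0.7, 0.1, 0.2, 0.8)$quadrant, "IV")
  expect_true(coc_distinct(q1, coc_locus(0.1, 0.7, 0.8, 0.2)))
  expect_false(coc_distinct(q1, coc_locus(0.6, 0.2, 0.9, 0.2)))
  expect_true(is.na(coc_distinct(q1, l0)))
})

test_that("fly loci from a step-function spectrum match a fine-grid oracle", {
  wl <- 300:700
  peaks <- c(330, 450, 350, 530)
  r <- gaussian_system("coc", peaks = peaks)
  refl <- ifelse(wl >= 480, 70, 10)  # step at 480 nm
  E <- excitation(quantum_catch(refl, r))
  loc <- coc_locus(E[["R7p"]], E[["R8p"]], E[["R7y"]], E[["R8y"]])
  refl_fun <- function(l) ifelse(l >= 480, 70, 10)
  Eo <- vapply(peaks, function(p) {
    P <- qc_oracle(function(l) exp(-((l - p) / 30)^2 / 2), refl_fun,
                   function(l) rep(1, length(l)), function(l) rep(25, length(l)))
    P / (P + 1)
  }, numeric(1))
  # a 1 nm trapezoid meets a 0.1 nm oracle less tightly across the
  # discontinuity than for smooth curves; 0.01 in opponent units
  expect_lt(abs(loc$x - (Eo[1] - Eo[2])), 0.01)
  expect_lt(abs(loc$y - (Eo[3] - Eo[4])), 0.01)
})

test_that("colour distance is a metric within one model and rejects mixing", {
  a <- hexagon_locus(0, 0, 1)
  o <- hexagon_locus(0.5, 0.5, 0.5)
  expect_equal(colour_distance(o, a), 1, tolerance = 1e-4)  # unit vertex
  expect_equal(colour_distance(a, a), 0)
  set.seed(31)
  loci <- replicate(12, {
    e <- runif(3); hexagon_locus(e[1], e[2], e[3])
  }, simplify = FALSE)
  for (i in 1:11) {
    d_ab <- colour_distance(loci[[i]], loci[[i + 1]])
    expect_equal(d_ab, colour_distance(loci[[i + 1]], loci[[i]]))  # symmetry
    expect_equal(d_ab, sqrt((loci[[i]]$x - loci[[i + 1]]$x)^2 +
                              (loci[[i]]$y - loci[[i + 1]]$y)^2))
    # triangle inequality via a third locus
    k <- if (i < 11) i + 2 else 1
    expect_lte(d_ab, colour_distance(loci[[i]], loci[[k]]) +
                 colour_distance(loci[[k]], loci[[i + 1]]) + 1e-12)
  }
  fly <- coc_locus(0.7, 0.2, 0.8, 0.1)
  expect_error(colour_distance(a, fly), "different colour models")
})

test_that("achromatic contrast is the green-excitation difference, bee model only", {
  a <- hexagon_locus(0.2, 0.3, 0.75)
  b <- hexagon_locus(0.6, 0.1, 0.5)
  expect_equal(achromatic_contrast(a, b), 0.25)
  expect_equal(achromatic_contrast(a, b), achromatic_contrast(b, a))
  expect_equal(achromatic_contrast(a, a), 0)
  fly <- coc_locus(0.7, 0.2, 0.8, 0.1)
  expect_error(achromatic_contrast(a, fly), "green receptor")
})

test_that("bootstrapped group colour distances estimate centroid separation", {
  one <- data.frame(x = 0.1, y = 0.2)
  same <- bootstrap_group_distance(one, one, n_boot = 50, seed = 3)
  expect_equal(same$mean_distance, 0)
  expect_equal(c(same$ci_low, same$ci_high), c(0, 0))
  set.seed(8)
  ga <- data.frame(x = rnorm(50, 0, 0.02), y = rnorm(50, 0, 0.02))
  gb <- data.frame(x = rnorm(50, 0.2, 0.02), y = rnorm(50, 0, 0.02))
  r1 <- bootstrap_group_distance(ga, gb, n_boot = 400, seed = 7)
  # point estimate is the centroid distance, independent of n_boot
  cd <- sqrt(sum((colMeans(ga) - colMeans(gb))^2))
  expect_equal(r1$mean_distance, cd)
  expect_equal(bootstrap_group_distance(ga, gb, n_boot = 5, seed = 1)$mean_distance, cd)
  expect_equal(r1$mean_distance, 0.2, tolerance = 0.02)
  expect_true(r1$ci_low <= r1$mean_distance && r1$mean_distance <= r1$ci_high)
  # bit-for-bit reproducible given the seed
  r2 <- bootstrap_group_distance(ga, gb, n_boot = 400, seed = 7)
  expect_identical(r1, r2)
  expect_error(bootstrap_group_distance(ga[0, ], gb), "non-empty")
})

test_that("full spectrum-to-locus chain runs for both packaged systems", {
  sc <- build_scenario()
  s <- sample_spectra(sc, "albidus", n = 3, seed = 2)
  bee <- colour_loci(s, bee_receptor_system())
  expect_equal(nrow(bee), 3)
  expect_true(all(c("UV", "B", "G", "x", "y") %in% names(bee)))
  fly <- colour_loci(s, fly_receptor_system())
  expect_true(all(fly$quadrant %in% c("I", "II", "III", "IV", "origin/axis")))
})

test_that("receptor-system bundles round-trip through CSV directories", {
  r <- gaussian_system("coc")
  d <- tempfile()
  write_receptor_system(r, d)
  r2 <- read_receptor_system(d)
  expect_equal(r2$sensitivities, r$sensitivities)
  expect_equal(r2$background, r$background)
  expect_equal(r2$model_kind, r$model_kind)
})
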