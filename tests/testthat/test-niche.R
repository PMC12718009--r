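test_that("occurrence quality filter is strict on accuracy and geoprivacy", {
  pts <- data.frame(ecotype = "e", lon = 1:4, lat = 1:4,
                    accuracy_m = c(100, 99, 20, NA),
                    geoprivacy = c("open", "open", "obscured", "open"))
  kept <- filter_occurrences(pts)
  expect_equal(kept$lon, 2)        # 100 fails (strict <), obscured fails, NA fails
  expect_warning(filter_occurrences(pts[1, ]), "no occurrence")
  expect_equal(nrow(filter_occurrences(pts, require_open = FALSE)), 2)
})

test_that("correlation pruning drops |r| > threshold greedily and keeps exact ties", {
  set.seed(15)
  n <- 400
  a <- rnorm(n)
  dup <- a                                        # r = 1 with a
  b <- rnorm(n)
  # construct a layer with |r| = 0.69 exactly against a
  e <- residuals(lm(rnorm(n) ~ a))
  exact <- 0.69 * a / sd(a) + sqrt(1 - 0.69^2) * e / sd(e)
  m <- cbind(a = a, dup = dup, b = b, exact = exact)
  kept <- prune_correlated(m, threshold = 0.69)
  expect_false("dup" %in% kept)
  expect_true(all(c("a", "b", "exact") %in% kept))  # strict >: 0.69 retained
  # independent noise layers: retained set matches brute-force pairwise check
  set.seed(16)
  noise <- matrix(rnorm(n * 6), ncol = 6,
                  dimnames = list(NULL, paste0("L", 1:6)))
  kept2 <- prune_correlated(noise, threshold = 0.69)
  expect_equal(kept2, colnames(noise), ignore_attr = TRUE)
  expect_true(all(abs(cor(noise)[upper.tri(diag(6))]) <= 0.69))
  # constant layer: flagged, retained by convention
  m3 <- cbind(a = a, const = rep(1, n))
  kept3 <- prune_correlated(m3)
  expect_true("const" %in% kept3)
  expect_equal(attr(kept3, "constant"), "const")
  # priority order decides which member of a correlated pair survives
  kept4 <- prune_correlated(m[, c("a", "dup")], priority = c("dup", "a"))
  expect_equal(as.character(kept4), "dup")
})

test_that("point extraction returns nearest-cell values and flags nodata", {
  v <- matrix(seq_len(20), nrow = 4, ncol = 5)  # row 1 = north
  v[2, 3] <- NA
  g <- env_grid(v, xll = 10, yll = 20, cellsize = 2)
  pts <- data.frame(lon = c(11, 15, 19), lat = c(27, 25, 21))
  ex <- extract_env(pts, list(layer = g))
  # oracle by direct index arithmetic
  col <- floor((pts$lon - 10) / 2) + 1
  row <- 4 - (floor((pts$lat - 20) / 2) + 1) + 1
  expect_equal(ex$layer, v[cbind(row, col)])
  expect_equal(ex$nodata, is.na(v[cbind(row, col)]))
  expect_error(extract_env(data.frame(lon = 9, lat = 21), list(layer = g)),
               "outside")
  set.seed(17)
  rpts <- data.frame(lon = runif(50, 10, 19.9), lat = runif(50, 20, 27.9))
  exr <- extract_env(rpts, list(layer = g))
  colr <- floor((rpts$lon - 10) / 2) + 1
  rowr <- 4 - (floor((rpts$lat - 20) / 2) + 1) + 1
  expect_equal(exr$layer, v[cbind(rowr, colr)])
})

test_that("rank-based AUC equals the pairwise-comparison probability", {
  expect_equal(auc_score(c(0.8, 0.9), c(0.1, 0.2)), 1)
  set.seed(18)
  p <- rnorm(40, 1); b <- rnorm(60)
  brute <- mean(outer(p, b, function(x, y) (x > y) + 0.5 * (x == y)))
  expect_equal(auc_score(p, b), brute)
  expect_equal(auc_score(b, p), 1 - auc_score(p, b))  # label antisymmetry
  # ties count one half
  expect_equal(auc_score(c(1, 1), c(1, 0)), 0.75)
  expect_error(auc_score(numeric(0), b), "non-empty")
})

test_that("equal sensitivity-specificity threshold follows the stated tie rules", {
  expect_equal(equal_ss_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  expect_equal(equal_ss_threshold(0.7, 0.3), 0.7)
  # chosen threshold attains the brute-force minimum of |sens - spec|
  set.seed(19)
  for (i in 1:10) {
    p <- runif(30); b <- runif(30)
    t_hat <- equal_ss_threshold(p, b)
    cand <- sort(unique(c(p, b)))
    d <- vapply(cand, function(t) abs(mean(p >= t) - mean(b < t)), numeric(1))
    expect_equal(abs(mean(p >= t_hat) - mean(b < t_hat)), min(d))
  }
  expect_error(equal_ss_threshold(numeric(0), 1), "non-empty")
})

test_that("binarization is monotone in the threshold and preserves nodata", {
  set.seed(20)
  v <- matrix(runif(200), 10)
  v[c(3, 50)] <- NA
  g <- env_grid(v)
  b0 <- binarize(g, 0)
  expect_equal(sum(b0$values == 1, na.rm = TRUE), sum(!is.na(v)))
  b_hi <- binarize(g, 1)
  expect_equal(sum(b_hi$values == 1, na.rm = TRUE), 0)
  for (t in c(0.2, 0.5, 0.8)) {
    bt <- binarize(g, t)
    expect_equal(sum(bt$values, na.rm = TRUE), sum(v >= t, na.rm = TRUE))
    expect_equal(is.na(bt$values), is.na(v))
    expect_equal(attr(bt, "threshold_used"), t)
  }
  counts <- sapply(seq(0, 1, 0.1), function(t) sum(binarize(g, t)$values, na.rm = TRUE))
  expect_true(all(diff(counts) <= 0))  # raising t never adds cells
})

test_that("overlap summaries match a cell-by-cell oracle and conserve totals", {
  set.seed(22)
  va <- matrix(rbinom(600, 1, 0.4), 20)
  vb <- matrix(rbinom(600, 1, 0.4), 20)
  va[1:5] <- NA; vb[3:8] <- NA
  a <- env_grid(va, cellsize = 1000); b <- env_grid(vb, cellsize = 1000)
  ov <- overlap_summary(a, b)
  ok <- !is.na(va) & !is.na(vb)
  expect_equal(ov$shared, sum(ok & va == 1 & vb == 1))
  expect_equal(ov$unshared_a, sum(ok & va == 1 & vb == 0))
  expect_equal(ov$unshared_b, sum(ok & va == 0 & vb == 1))
  expect_equal(ov$shared + ov$unshared_a, sum(ok & va == 1))  # conserved totals
  # identical and disjoint ranges
  same <- overlap_summary(a, a)
  expect_equal(same$unshared_a, 0); expect_equal(same$unshared_b, 0)
  vd <- matrix(0, 20, 30); vd[va == 0] <- 1
  disj <- overlap_summary(a, env_grid(vd, cellsize = 1000))
  expect_equal(disj$shared, 0)
  expect_error(overlap_summary(a, env_grid(vb[1:10, ], cellsize = 1000)),
               "geometry")
  expect_warning(overlap_summary(env_grid(va, 18, -33, 0.01),
                                 env_grid(vb, 18, -33, 0.01)), "geographic")
})

test_that("ESRI ASCII grids round-trip including nodata", {
  set.seed(23)
  v <- matrix(round(runif(48), 3), 6)
  v[c(2, 17)] <- NA
  g <- env_grid(v, xll = 18.2, yll = -34.1, cellsize = 0.25)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  g2 <- read_ascii_grid(f)
  expect_equal(g2$values, g$values)
  expect_equal(c(g2$xll, g2$yll, g2$cellsize), c(18.2, -34.1, 0.25))
})

test_that("grid resampling aligns geometries (identity and coarsening)", {
  set.seed(24)
  v <- matrix(runif(400), 20)
  g <- env_grid(v, 0, 0, 1)
  same <- resample_grid(g, g, "nearest")
  expect_equal(same$values, v)
  # binary coarsening by nearest neighbour keeps values in {0,1}
  b <- env_grid(matrix(rbinom(400, 1, 0.5), 20), 0, 0, 1)
  target <- env_grid(matrix(0, 10, 10), 0, 0, 2)
  rb <- resample_grid(b, target, "nearest")
  expect_true(all(rb$values %in% c(0, 1)))
  # bilinear of a linear field is exact in the interior
  lin <- outer(19.5:0.5, 0.5:19.5, function(y, x) 2 * x + 3 * y)
  gl <- env_grid(lin, 0, 0, 1)
  tl <- env_grid(matrix(0, 9, 9), 1, 1, 2)
  rl <- resample_grid(gl, tl, "bilinear")
  cx <- 1 + (seq_len(9) - 0.5) * 2
  cy <- 1 + (9 - seq_len(9) + 0.5) * 2
  expected <- outer(cy, cx, function(y, x) 2 * x + 3 * y)
  expect_equal(rl$values, expected)
})
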