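#' Gridded environmental / suitability layer
#'
#' A light raster container: a numeric matrix (row 1 = northernmost row, as
#' in the ESRI ASCII convention) with a lower-left corner, square cell size
#' and `NA` as the nodata mask. Values may be environmental measurements,
#' habitat-suitability probabilities or binary presence.
#'
#' Cell areas are treated as equal; a warning is emitted for grids that look
#' geographic (cell size below 1 and coordinates within degree bounds) when
#' counting cells as areas.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (grid units).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, xll = 0, yll = 0, cellsize = 1) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells, cellsize %g, origin (%g, %g), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows of values, north first).
#'
#' @param path File path.
#' @param g An `env_grid` (for writing).
#' @param nodata Value written for `NA` cells.
#' @return `read_ascii_grid()` an `env_grid`; `write_ascii_grid()` invisibly
#'   `g`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  env_grid(m, xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
           cellsize = hdr$cellsize %||% 1)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "env_grid"))
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", g$xll), paste("yllcorner", g$yll),
           paste("cellsize", g$cellsize), paste("NODATA_value", nodata))
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(g)
}

#' Filter occurrence records for locational quality
#'
#' Keeps records with open geoprivacy and coordinate accuracy strictly below
#' `max_accuracy_m` metres. Missing accuracy fails the filter
#' (conservative).
#'
#' @param points Data frame with columns `accuracy_m` and (if
#'   `require_open`) `geoprivacy`.
#' @param max_accuracy_m Accuracy cut-off in metres (strict `<`).
#' @param require_open Require `geoprivacy == "open"`.
#' @return The retained rows; warns if none survive.
#' @export
filter_occurrences <- function(points, max_accuracy_m = 100, require_open = TRUE) {
  keep <- !is.na(points$accuracy_m) & points$accuracy_m < max_accuracy_m
  if (require_open) keep <- keep & !is.na(points$geoprivacy) & points$geoprivacy == "open"
  out <- points[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no occurrence records passed the filter")
  rownames(out) <- NULL
  out
}

#' Greedy pruning of correlated environmental layers
#'
#' Scans layers in a priority order and drops any layer whose absolute
#' Pearson correlation with an already-retained layer exceeds `threshold`
#' (strict `>`; a pair at exactly the threshold is kept). Correlations are
#' computed over jointly valid cells, or at supplied point locations.
#' All-constant layers have undefined correlation and are retained by
#' convention, with a flag.
#'
#' @param stack Named list of `env_grid` layers on one shared geometry, or a
#'   numeric matrix/data frame of per-point layer values (columns = layers).
#' @param threshold Absolute-correlation exclusion threshold.
#' @param priority Character vector giving the scan order (default: input
#'   order).
#' @return Character vector of retained layer names, with a `"constant"`
#'   attribute naming any degenerate layers.
#' @export
prune_correlated <- function(stack, threshold = 0.69, priority = NULL) {
  if (is.list(stack) && inherits(stack[[1]], "env_grid")) {
    geom_ok <- all(vapply(stack, same_geometry, logical(1), b = stack[[1]]))
    if (!geom_ok) stop("layers differ in geometry")
    m <- sapply(stack, function(g) as.vector(g$values))
  } else {
    m <- as.matrix(stack)
  }
  if (ncol(m) < 2) stop("need at least two layers")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  nm <- colnames(m)
  priority <- priority %||% nm
  stopifnot(setequal(priority, nm))
  sds <- apply(m, 2, stats::sd)
  constant <- nm[sds == 0]
  retained <- character(0)
  for (layer in priority) {
    if (sds[layer] == 0) {
      retained <- c(retained, layer)  # undefined r: kept by convention
      next
    }
    comparable <- retained[sds[retained] > 0]
    r <- if (length(comparable)) {
      abs(stats::cor(m[, layer], m[, comparable, drop = FALSE]))
    } else 0
    if (all(r <= threshold)) retained <- c(retained, layer)
  }
  attr(retained, "constant") <- constant
  retained
}

#' Extract layer values at point localities
#'
#' Nearest-cell lookup of every layer at every point. Points falling on
#' nodata in any layer are flagged so they can be excluded from downstream
#' statistics.
#'
#' @param points Data frame with columns `lon` and `lat` (grid coordinate
#'   units).
#' @param stack Named list of `env_grid` layers on one shared geometry.
#' @return Data frame: the input points, one column per layer, and a logical
#'   `nodata` flag.
#' @export
extract_env <- function(points, stack) {
  g0 <- stack[[1]]
  if (!all(vapply(stack, same_geometry, logical(1), b = g0))) {
    stop("layers differ in geometry")
  }
  nr <- nrow(g0$values); nc <- ncol(g0$values)
  col <- floor((points$lon - g0$xll) / g0$cellsize) + 1
  row_from_bottom <- floor((points$lat - g0$yll) / g0$cellsize) + 1
  row <- nr - row_from_bottom + 1  # matrix row 1 is the northern edge
  if (any(col < 1 | col > nc | row < 1 | row > nr)) {
    stop("point outside grid extent")
  }
  idx <- cbind(row, col)
  vals <- sapply(stack, function(g) g$values[idx])
  vals <- matrix(vals, nrow = nrow(points), dimnames = list(NULL, names(stack)))
  out <- cbind(as.data.frame(points), as.data.frame(vals))
  out$nodata <- apply(is.na(vals), 1, any)
  out
}

#' Rank-based AUC of suitability scores
#'
#' Probability that a random presence score exceeds a random background
#' score, with ties counted one half (the Mann-Whitney statistic scaled to
#' `[0, 1]`).
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Equal sensitivity-specificity threshold
#'
#' Over candidate thresholds (the unique observed scores), chooses the
#' threshold t minimizing `|sensitivity(t) - specificity(t)|` under the
#' presence rule `score >= t`. Ties are resolved by maximizing
#' sensitivity + specificity, then by the smallest t.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return The chosen threshold.
#' @export
equal_ss_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0) {
    stop("both score sets must be non-empty")
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  d <- abs(sens - spec)
  best <- which(d == min(d))
  if (length(best) > 1) {
    s <- (sens + spec)[best]
    best <- best[s == max(s)]
  }
  cand[best[1]]
}

#' Binarize a suitability surface
#'
#' Cells with suitability at or above the threshold become presence (1),
#' cells below become absence (0); nodata is preserved.
#'
#' @param surface An `env_grid` of suitability values in `[0, 1]`.
#' @param t Threshold in `[0, 1]`.
#' @return An `env_grid` of 0/1 presence with attribute `threshold_used`.
#' @export
binarize <- function(surface, t) {
  stopifnot(inherits(surface, "env_grid"), t >= 0, t <= 1)
  v <- surface$values
  out <- env_grid(ifelse(is.na(v), NA, as.numeric(v >= t)),
                  surface$xll, surface$yll, surface$cellsize)
  attr(out, "threshold_used") <- t
  out
}

#' Shared and unshared presence cells of two binary ranges
#'
#' Counts, over jointly valid cells, the cells where both ranges are present
#' (shared, S), where only range a is present (U_a) and where only range b
#' is present (U_b). These counts are the raw material of the ecogeographic
#' barrier.
#'
#' @param a,b Binary `env_grid` ranges on identical geometry.
#' @return List with `shared`, `unshared_a`, `unshared_b`.
#' @export
overlap_summary <- function(a, b) {
  stopifnot(inherits(a, "env_grid"), inherits(b, "env_grid"))
  if (!same_geometry(a, b)) stop("geometry mismatch: resample first")
  if (looks_geographic(a)) {
    warning("grid looks geographic (degrees): cell counts are not equal-area")
  }
  va <- a$values; vb <- b$values
  ok <- !is.na(va) & !is.na(vb)
  list(shared = sum(va[ok] == 1 & vb[ok] == 1),
       unshared_a = sum(va[ok] == 1 & vb[ok] == 0),
       unshared_b = sum(va[ok] == 0 & vb[ok] == 1))
}

looks_geographic <- function(g) {
  g$cellsize < 0.5 && g$xll >= -180 && g$xll <= 180 &&
    g$yll >= -90 && g$yll <= 90 &&
    (g$yll + nrow(g$values) * g$cellsize) <= 90
}

#' Align a grid onto a target geometry
#'
#' Nearest-neighbour resampling for binary/categorical layers, bilinear for
#' continuous ones. Cells of the target whose source location falls outside
#' the source extent become nodata.
#'
#' @param g Source `env_grid`.
#' @param target `env_grid` defining the output geometry.
#' @param method `"nearest"` or `"bilinear"`.
#' @return An `env_grid` on the target geometry.
#' @export
resample_grid <- function(g, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  nr <- nrow(target$values); nc <- ncol(target$values)
  # centre coordinates of every target cell
  cx <- target$xll + (seq_len(nc) - 0.5) * target$cellsize
  cy <- target$yll + (nr - seq_len(nr) + 0.5) * target$cellsize
  snr <- nrow(g$values); snc <- ncol(g$values)
  fx <- (rep(cx, each = nr) - g$xll) / g$cellsize   # fractional source col
  fy <- (rep(cy, times = nc) - g$yll) / g$cellsize  # fractional source row (from bottom)
  out <- rep(NA_real_, nr * nc)
  if (method == "nearest") {
    sc <- floor(fx) + 1
    sr <- snr - floor(fy)
    ok <- sc >= 1 & sc <= snc & sr >= 1 & sr <= snr
    out[ok] <- g$values[cbind(sr[ok], sc[ok])]
  } else {
    x0 <- floor(fx - 0.5); y0 <- floor(fy - 0.5)
    wx <- fx - 0.5 - x0;   wy <- fy - 0.5 - y0
    ok <- x0 >= 0 & (x0 + 2) <= snc & y0 >= 0 & (y0 + 2) <= snr
    gv <- function(ry, cx2) g$values[cbind(snr - ry, cx2 + 1)]
    i <- which(ok)
    v00 <- gv(y0[i], x0[i]);     v10 <- gv(y0[i], x0[i] + 1)
    v01 <- gv(y0[i] + 1, x0[i]); v11 <- gv(y0[i] + 1, x0[i] + 1)
    out[i] <- (1 - wx[i]) * (1 - wy[i]) * v00 + wx[i] * (1 - wy[i]) * v10 +
      (1 - wx[i]) * wy[i] * v01 + wx[i] * wy[i] * v11
  }
  env_grid(matrix(out, nrow = nr, ncol = nc), target$xll, target$yll,
           target$cellsize)
}
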