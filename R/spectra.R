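#' Construct a set of reflectance spectra on a common wavelength grid
#'
#' A `spectrum_set` holds labelled floral reflectance curves, all linearly
#' interpolated onto a shared 1 nm wavelength grid inside 300--700 nm, plus
#' per-measurement metadata (ecotype, population, flower part). Reflectance is
#' in percent (nominally 0--100; raw spectrometer output may dip below 0, see
#' [fix_negatives()]).
#'
#' @param wavelengths Numeric vector of strictly increasing wavelengths (nm)
#'   covering the target grid range.
#' @param reflectance Numeric matrix, one column per measurement, rows matching
#'   `wavelengths`.
#' @param metadata Data frame with one row per measurement and at least the
#'   columns `id`, `ecotype`, `population`, `flower_part`. `id` must match
#'   `colnames(reflectance)`.
#' @param grid Target wavelength grid (default `300:700`, 1 nm steps).
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavelengths` (the common grid), `reflectance` (matrix, columns named by
#'   measurement id) and `metadata`.
#' @export
spectrum_set <- function(wavelengths, reflectance, metadata, grid = 300:700) {
  if (is.null(dim(reflectance))) {
    reflectance <- matrix(reflectance, ncol = 1)
  }
  if (length(wavelengths) != nrow(reflectance)) {
    stop("wavelengths and reflectance rows differ in length")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(reflectance))) stop("reflectance must be finite")
  if (min(grid) < min(wavelengths) || max(grid) > max(wavelengths)) {
    stop("wavelength grid not covered by measured range [",
         min(wavelengths), ", ", max(wavelengths), "] nm")
  }
  res <- apply(reflectance, 2, function(y) {
    stats::approx(wavelengths, y, xout = grid)$y
  })
  res <- matrix(res, nrow = length(grid), dimnames = list(NULL, colnames(reflectance)))
  metadata <- as.data.frame(metadata)
  req <- c("id", "ecotype", "population", "flower_part")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  parts <- c("tepal", "median_centre", "median_guide",
             "lateral_centre", "lateral_guide", "gullet")
  bad <- setdiff(unique(metadata$flower_part), parts)
  if (length(bad)) stop("unknown flower_part: ", paste(bad, collapse = ", "))
  if (is.null(colnames(res))) colnames(res) <- metadata$id
  if (!all(colnames(res) %in% metadata$id)) {
    stop("every spectrum id needs a metadata row")
  }
  metadata <- metadata[match(colnames(res), metadata$id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(wavelengths = as.numeric(grid), reflectance = res,
                 metadata = metadata),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", ncol(x$reflectance), "spectra on",
      length(x$wavelengths), "nm grid [",
      min(x$wavelengths), "-", max(x$wavelengths), "nm ]\n")
  cat("  ecotypes:", paste(unique(x$metadata$ecotype), collapse = ", "), "\n")
  invisible(x)
}

#' Read spectra and metadata from CSV files
#'
#' The spectra file is wide: first column `wavelength_nm`, remaining columns
#' one measurement each, named by measurement id. The metadata file has
#' columns `id,ecotype,population,flower_part`.
#'
#' @param spectra_csv Path to the wide spectra CSV.
#' @param metadata_csv Path to the metadata CSV.
#' @param grid Target wavelength grid passed to [spectrum_set()].
#' @return A `spectrum_set`.
#' @export
read_spectra <- function(spectra_csv, metadata_csv, grid = 300:700) {
  sp <- utils::read.csv(spectra_csv, check.names = FALSE)
  if (names(sp)[1] != "wavelength_nm") {
    stop("first column of spectra CSV must be 'wavelength_nm'")
  }
  wl <- sp[[1]]
  if (is.unsorted(wl, strictly = TRUE)) stop("non-monotone wavelengths in ", spectra_csv)
  md <- utils::read.csv(metadata_csv, check.names = FALSE)
  spectrum_set(wl, as.matrix(sp[, -1, drop = FALSE]), md, grid = grid)
}

#' Write a spectrum set back to CSV
#'
#' Inverse of [read_spectra()]; round-trips the common-grid representation
#' exactly.
#'
#' @param s A `spectrum_set`.
#' @param spectra_csv,metadata_csv Output paths.
#' @return Invisibly, `s`.
#' @export
write_spectra <- function(s, spectra_csv, metadata_csv) {
  stopifnot(inherits(s, "spectrum_set"))
  out <- data.frame(wavelength_nm = s$wavelengths, check.names = FALSE)
  out <- cbind(out, as.data.frame(s$reflectance, check.names = FALSE))
  utils::write.csv(out, spectra_csv, row.names = FALSE)
  utils::write.csv(s$metadata, metadata_csv, row.names = FALSE)
  invisible(s)
}

#' Correct negative reflectance values
#'
#' Spectrometer noise can push reflectance slightly below zero. `addmin` adds
#' the absolute value of each spectrum's minimum to the whole curve, but only
#' for curves whose minimum is negative (the usual spectral-processing
#' behaviour); `clamp` truncates negative values at zero. Non-negative curves
#' are returned unchanged under both methods.
#'
#' @param s A `spectrum_set`.
#' @param method `"addmin"` (default) or `"clamp"`.
#' @return A `spectrum_set` with non-negative reflectance.
#' @export
fix_negatives <- function(s, method = c("addmin", "clamp")) {
  stopifnot(inherits(s, "spectrum_set"))
  method <- match.arg(method)
  r <- s$reflectance
  if (method == "addmin") {
    mins <- apply(r, 2, min)
    neg <- mins < 0
    if (any(neg)) r[, neg] <- sweep(r[, neg, drop = FALSE], 2, mins[neg], "-")
  } else {
    r[r < 0] <- 0
  }
  s$reflectance <- r
  s
}

#' Pointwise group mean and standard error of spectra
#'
#' Aggregates the curves of each group (defined by one or more metadata
#' columns) into a pointwise mean and standard error (sd / sqrt(n)) per
#' wavelength, the summaries used in reflectance aggregation plots.
#'
#' @param s A `spectrum_set`.
#' @param by Character vector of metadata column names defining the groups
#'   (default `"ecotype"`).
#' @return A data frame with columns `group`, the `by` columns, `n`,
#'   `singleton` (flag: groups of one curve have s.e. 0), `wavelength_nm`,
#'   `mean`, `se`.
#' @export
aggregate_group <- function(s, by = "ecotype") {
  stopifnot(inherits(s, "spectrum_set"))
  miss <- setdiff(by, names(s$metadata))
  if (length(miss)) stop("unknown metadata columns: ", paste(miss, collapse = ", "))
  key <- interaction(s$metadata[by], drop = TRUE, sep = "/")
  out <- lapply(levels(key), function(g) {
    cols <- which(key == g)
    if (!length(cols)) stop("empty group: ", g)
    m <- s$reflectance[, cols, drop = FALSE]
    mu <- rowMeans(m)
    se <- if (ncol(m) == 1L) rep(0, nrow(m)) else apply(m, 1, stats::sd) / sqrt(ncol(m))
    cbind(data.frame(group = g,
                     s$metadata[cols[1], by, drop = FALSE],
                     n = ncol(m), singleton = ncol(m) == 1L,
                     wavelength_nm = s$wavelengths, row.names = NULL),
          data.frame(mean = mu, se = se))
  })
  do.call(rbind, out)
}
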