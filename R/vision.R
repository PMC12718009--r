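#' Visual pigment absorbance template
#'
#' Standard A1 visual-pigment nomogram (alpha plus beta band) used to build
#' smooth receptor sensitivity curves from a single peak wavelength. Used by
#' the packaged bee and fly receptor systems; any empirically measured curve
#' can be supplied instead via [receptor_system()].
#'
#' @param lambda_max Peak absorbance wavelength (nm).
#' @param wavelengths Wavelength grid (nm).
#' @return Numeric vector of relative sensitivities in `[0, 1]`.
#' @export
pigment_template <- function(lambda_max, wavelengths = 300:700) {
  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelengths - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

#' Daylight-like illuminant (synthetic D65 approximation)
#'
#' A smooth spline through coarse anchor points of the standard D65 daylight
#' distribution, normalized to 100 at 560 nm. This is a synthetic stand-in
#' curve, adequate for von Kries-normalized modelling (where the illuminant
#' largely cancels); substitute a measured illuminant for published work.
#'
#' @param wavelengths Wavelength grid (nm).
#' @return Numeric vector of relative spectral power.
#' @export
d65_illuminant <- function(wavelengths = 300:700) {
  wl <- seq(300, 700, by = 20)
  sp <- c(0.3, 20.2, 39.9, 46.6, 50.0, 82.8, 93.4, 104.9, 117.8, 115.9,
          109.4, 104.8, 104.4, 100.0, 95.8, 90.0, 87.7, 83.7, 80.2, 78.3, 71.6)
  pmax(stats::spline(wl, sp, xout = wavelengths)$y, 0)
}

#' Green-foliage adapting background (synthetic leaf reflectance)
#'
#' Smooth synthetic green-leaf reflectance: low in the UV/blue, a green bump
#' near 550 nm, low red, rising at the red edge. Percent units.
#'
#' @param wavelengths Wavelength grid (nm).
#' @return Numeric vector of reflectance (percent).
#' @export
green_leaf_background <- function(wavelengths = 300:700) {
  wl <- c(300, 350, 400, 450, 500, 550, 600, 650, 680, 700)
  rf <- c(3.5, 3.8, 4.0, 4.2, 7.0, 15.0, 8.0, 5.5, 4.5, 9.0)
  pmax(stats::spline(wl, rf, xout = wavelengths)$y, 0.1)
}

#' Construct a receptor system
#'
#' Bundles receptor sensitivity curves with an illuminant and an adapting
#' background, all resampled to a common 1 nm grid. A bee (`hexagon`) system
#' has exactly three receptors (UV, B, G); a fly (`coc`) system exactly four
#' (R7p, R8p, R7y, R8y).
#'
#' @param sensitivities Numeric matrix (wavelengths x receptors) of
#'   non-negative sensitivity curves, columns named.
#' @param illuminant Numeric vector, illuminant spectral power on the grid.
#' @param background Numeric vector, adapting background reflectance.
#' @param model_kind `"hexagon"` or `"coc"`.
#' @param wavelengths Wavelength grid the curves are defined on.
#' @return An object of class `receptor_system`.
#' @export
receptor_system <- function(sensitivities, illuminant, background,
                            model_kind = c("hexagon", "coc"),
                            wavelengths = 300:700) {
  model_kind <- match.arg(model_kind)
  sensitivities <- as.matrix(sensitivities)
  n_expect <- if (model_kind == "hexagon") 3L else 4L
  if (ncol(sensitivities) != n_expect) {
    stop(model_kind, " system needs exactly ", n_expect, " receptors")
  }
  if (is.null(colnames(sensitivities))) {
    colnames(sensitivities) <- if (model_kind == "hexagon") {
      c("UV", "B", "G")
    } else {
      c("R7p", "R8p", "R7y", "R8y")
    }
  }
  if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
  stopifnot(nrow(sensitivities) == length(wavelengths),
            length(illuminant) == length(wavelengths),
            length(background) == length(wavelengths))
  structure(list(wavelengths = as.numeric(wavelengths),
                 receptor_names = colnames(sensitivities),
                 sensitivities = sensitivities,
                 illuminant = as.numeric(illuminant),
                 background = as.numeric(background),
                 model_kind = model_kind),
            class = "receptor_system")
}

#' Packaged trichromatic bee system (colour hexagon)
#'
#' UV/blue/green receptor sensitivities built from the pigment nomogram at
#' honeybee-like peaks (344, 436, 556 nm), with the packaged daylight
#' illuminant and green-foliage background. Template curves are synthetic;
#' tests of model correctness use independent Gaussian systems.
#'
#' @param wavelengths Wavelength grid (nm).
#' @return A `receptor_system` with `model_kind = "hexagon"`.
#' @export
bee_receptor_system <- function(wavelengths = 300:700) {
  s <- sapply(c(UV = 344, B = 436, G = 556), pigment_template,
              wavelengths = wavelengths)
  receptor_system(s, d65_illuminant(wavelengths),
                  green_leaf_background(wavelengths),
                  "hexagon", wavelengths)
}

#' Packaged four-receptor fly system (colour-opponent coding)
#'
#' Pale and yellow ommatidial receptor pairs (R7p/R8p, R7y/R8y) built from
#' the pigment nomogram at hoverfly-like peaks (330, 450, 350, 530 nm).
#' Synthetic template curves, see [bee_receptor_system()].
#'
#' @param wavelengths Wavelength grid (nm).
#' @return A `receptor_system` with `model_kind = "coc"`.
#' @export
fly_receptor_system <- function(wavelengths = 300:700) {
  s <- sapply(c(R7p = 330, R8p = 450, R7y = 350, R8y = 530), pigment_template,
              wavelengths = wavelengths)
  receptor_system(s, d65_illuminant(wavelengths),
                  green_leaf_background(wavelengths),
                  "coc", wavelengths)
}

#' Read / write a receptor-system bundle
#'
#' A bundle is a directory of two-column CSV curves (`wavelength_nm,value`)
#' named `illuminant.csv`, `background.csv` and one `<receptor>.csv` per
#' receptor, plus a `manifest.csv` with columns `receptor` (ordered) and a
#' single `model_kind` value.
#'
#' @param dir Bundle directory.
#' @param r A `receptor_system` (for writing).
#' @param wavelengths Target grid for reading.
#' @return `read_receptor_system()` a `receptor_system`;
#'   `write_receptor_system()` invisibly `r`.
#' @export
read_receptor_system <- function(dir, wavelengths = 300:700) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  curve <- function(name) {
    d <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
    stats::approx(d[[1]], d[[2]], xout = wavelengths)$y
  }
  s <- sapply(man$receptor, curve)
  receptor_system(s, curve("illuminant"), curve("background"),
                  man$model_kind[1], wavelengths)
}

#' @rdname read_receptor_system
#' @export
write_receptor_system <- function(r, dir) {
  stopifnot(inherits(r, "receptor_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(name, v) {
    utils::write.csv(data.frame(wavelength_nm = r$wavelengths, value = v),
                     file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  for (nm in r$receptor_names) wr(nm, r$sensitivities[, nm])
  wr("illuminant", r$illuminant)
  wr("background", r$background)
  utils::write.csv(data.frame(receptor = r$receptor_names,
                              model_kind = r$model_kind),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(r)
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Von Kries-normalized quantum catch
#'
#' Receptor quantum catch P = R * integral of S_i(l) I(l) D(l) over
#' 300--700 nm (trapezoidal rule on the system's grid), where S_i is the
#' receptor sensitivity, I the stimulus reflectance, D the illuminant, and R
#' the von Kries factor chosen per receptor so that the adapting background
#' has catch exactly 1.
#'
#' @param reflectance Numeric vector of stimulus reflectance on the system's
#'   wavelength grid.
#' @param r A `receptor_system`.
#' @param receptor Receptor name; if missing, catches for all receptors.
#' @return Named numeric vector of quantum catches (dimensionless).
#' @export
quantum_catch <- function(reflectance, r, receptor = NULL) {
  stopifnot(inherits(r, "receptor_system"),
            length(reflectance) == length(r$wavelengths))
  names <- receptor %||% r$receptor_names
  bad <- setdiff(names, r$receptor_names)
  if (length(bad)) stop("receptor not in system: ", paste(bad, collapse = ", "))
  vapply(names, function(nm) {
    s <- r$sensitivities[, nm]
    bg <- trapezoid(r$wavelengths, s * r$illuminant * r$background)
    if (bg <= 0) stop("background catch is zero for receptor ", nm,
                      ": von Kries normalization undefined")
    trapezoid(r$wavelengths, s * r$illuminant * reflectance) / bg
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hyperbolic receptor excitation
#'
#' E = P / (P + 1): monotone saturating transform of the quantum catch, with
#' E(0) = 0, E(1) = 0.5 (the adapting background) and E -> 1 as P grows.
#'
#' @param P Quantum catch (non-negative).
#' @return Excitation in `[0, 1)`.
#' @export
excitation <- function(P) {
  if (any(P < 0)) stop("quantum catch must be non-negative")
  P / (P + 1)
}

new_locus <- function(excitations, x, y, model_kind, quadrant = NA_character_) {
  structure(list(excitations = excitations, x = x, y = y,
                 model_kind = model_kind, quadrant = quadrant),
            class = "colour_locus")
}

#' @export
print.colour_locus <- function(x, ...) {
  cat(sprintf("colour_locus [%s] x = %.4f, y = %.4f%s\n", x$model_kind, x$x,
              x$y,
              if (!is.na(x$quadrant)) paste0(" (quadrant ", x$quadrant, ")") else ""))
  invisible(x)
}

check_excitation <- function(...) {
  e <- c(...)
  if (any(e < 0 | e > 1)) stop("excitations must lie in [0, 1]")
  e
}

#' Bee colour-hexagon locus
#'
#' Maps the three receptor excitations into the colour hexagon:
#' x = sin(60 deg) * (E_G - E_UV), y = E_B - (E_G + E_UV) / 2. The adapting
#' background (all E = 0.5) maps to the origin; all loci for excitations in
#' `[0, 1]` lie within unit distance of the origin.
#'
#' @param e_uv,e_b,e_g Excitations of the UV, blue and green receptors.
#' @return A `colour_locus` with `model_kind = "hexagon"`.
#' @export
hexagon_locus <- function(e_uv, e_b, e_g) {
  check_excitation(e_uv, e_b, e_g)
  new_locus(c(UV = e_uv, B = e_b, G = e_g),
            x = sin(pi / 3) * (e_g - e_uv),
            y = e_b - (e_g + e_uv) / 2,
            model_kind = "hexagon")
}

#' Fly colour-opponent-coding locus
#'
#' Opponent signals of the pale and yellow receptor pairs:
#' x = E_R7p - E_R8p, y = E_R7y - E_R8y. The quadrant of the Cartesian plane
#' is the fly's colour category; loci on an axis (either opponent signal
#' exactly zero) are flagged `"origin/axis"` rather than silently assigned.
#'
#' @param e_r7p,e_r8p,e_r7y,e_r8y Excitations of the four fly receptors.
#' @return A `colour_locus` with `model_kind = "coc"` and a `quadrant` label
#'   in `{"I","II","III","IV","origin/axis"}`.
#' @export
coc_locus <- function(e_r7p, e_r8p, e_r7y, e_r8y) {
  check_excitation(e_r7p, e_r8p, e_r7y, e_r8y)
  x <- e_r7p - e_r8p
  y <- e_r7y - e_r8y
  q <- if (x == 0 || y == 0) {
    "origin/axis"
  } else if (x > 0 && y > 0) "I" else if (x < 0 && y > 0) "II" else
    if (x < 0 && y < 0) "III" else "IV"
  new_locus(c(R7p = e_r7p, R8p = e_r8p, R7y = e_r7y, R8y = e_r8y),
            x = x, y = y, model_kind = "coc", quadrant = q)
}

#' Euclidean colour distance between two loci
#'
#' Distances within one model's plane proxy discriminability: larger
#' distances are more perceptible. Mixing loci from different models is an
#' error.
#'
#' @param a,b `colour_locus` objects of the same `model_kind`.
#' @return Non-negative distance in model units.
#' @export
colour_distance <- function(a, b) {
  stopifnot(inherits(a, "colour_locus"), inherits(b, "colour_locus"))
  if (a$model_kind != b$model_kind) {
    stop("cannot compare loci from different colour models")
  }
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Whether two fly loci are categorically distinct
#'
#' Under quadrant-categorical colour vision, loci in different quadrants are
#' perceptibly different colours; loci within the same quadrant are not. With
#' a positive `threshold`, within-quadrant pairs further apart than the
#' threshold also count as distinct (finer discrimination reported for some
#' hoverflies).
#'
#' @param a,b `colour_locus` objects with `model_kind = "coc"`.
#' @param threshold Within-quadrant discrimination distance (default 0 =
#'   quadrant-categorical only).
#' @return Logical; `NA` if either locus sits on an axis.
#' @export
coc_distinct <- function(a, b, threshold = 0) {
  stopifnot(a$model_kind == "coc", b$model_kind == "coc")
  if (a$quadrant == "origin/axis" || b$quadrant == "origin/axis") return(NA)
  if (a$quadrant != b$quadrant) return(TRUE)
  threshold > 0 && colour_distance(a, b) > threshold
}

#' Achromatic (green-receptor) contrast
#'
#' Brightness-channel contrast between two bee loci, the absolute difference
#' of their green-receptor excitations. Not defined for the fly model (no
#' behavioural evidence weighting fly achromatic vision).
#'
#' @param a,b `colour_locus` objects with `model_kind = "hexagon"`.
#' @return Non-negative contrast.
#' @export
achromatic_contrast <- function(a, b) {
  stopifnot(inherits(a, "colour_locus"), inherits(b, "colour_locus"))
  if (a$model_kind != "hexagon" || b$model_kind != "hexagon") {
    stop("achromatic contrast uses the bee green receptor (hexagon model only)")
  }
  abs(a$excitations[["G"]] - b$excitations[["G"]])
}

#' Colour loci for every spectrum in a set
#'
#' Runs the full chain (quantum catch, hyperbolic excitation, model
#' coordinates) for each measurement.
#'
#' @param s A `spectrum_set` on the system's wavelength grid.
#' @param r A `receptor_system`.
#' @return A data frame with one row per spectrum: `id`, metadata columns,
#'   one excitation column per receptor, `x`, `y` and (for the fly model)
#'   `quadrant`.
#' @export
colour_loci <- function(s, r) {
  stopifnot(inherits(s, "spectrum_set"), inherits(r, "receptor_system"))
  if (!isTRUE(all.equal(s$wavelengths, r$wavelengths))) {
    stop("spectrum set and receptor system are on different wavelength grids")
  }
  rows <- lapply(seq_len(ncol(s$reflectance)), function(i) {
    E <- excitation(quantum_catch(s$reflectance[, i], r))
    loc <- if (r$model_kind == "hexagon") {
      hexagon_locus(E[["UV"]], E[["B"]], E[["G"]])
    } else {
      coc_locus(E[["R7p"]], E[["R8p"]], E[["R7y"]], E[["R8y"]])
    }
    cbind(s$metadata[i, , drop = FALSE],
          as.data.frame(as.list(E)),
          data.frame(x = loc$x, y = loc$y, quadrant = loc$quadrant))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (r$model_kind == "hexagon") out$quadrant <- NULL
  out
}

#' Bootstrapped colour distance between two groups of loci
#'
#' Point estimate: Euclidean distance between the group centroids.
#' Confidence interval: 2.5/97.5 percentiles of the centroid distance over
#' `n_boot` within-group resamples (with replacement). Reproducible given
#' `seed`.
#'
#' @param group_a,group_b Data frames (or matrices) with columns `x` and `y`,
#'   e.g. subsets of [colour_loci()] output.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer RNG seed.
#' @param labels Optional character vector of two group labels.
#' @return A one-row data frame: `group_a`, `group_b`, `mean_distance`,
#'   `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
bootstrap_group_distance <- function(group_a, group_b, n_boot = 1000,
                                     seed = 1L, labels = c("a", "b")) {
  ga <- as.matrix(as.data.frame(group_a)[, c("x", "y")])
  gb <- as.matrix(as.data.frame(group_b)[, c("x", "y")])
  if (nrow(ga) == 0 || nrow(gb) == 0) stop("both groups must be non-empty")
  stopifnot(n_boot >= 1)
  cdist <- function(a, b) sqrt(sum((colMeans(a) - colMeans(b))^2))
  est <- cdist(ga, gb)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    cdist(ga[sample.int(nrow(ga), replace = TRUE), , drop = FALSE],
          gb[sample.int(nrow(gb), replace = TRUE), , drop = FALSE])
  }, numeric(1)))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(group_a = labels[1], group_b = labels[2], mean_distance = est,
             ci_low = ci[1], ci_high = ci[2], n_boot = n_boot, seed = seed)
}
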