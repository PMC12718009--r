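# Shared fixtures and independent oracles, built in code.

# Synthetic Gaussian receptor system on an arbitrary grid, so colour-model
# tests never depend on the packaged nomogram curves.
gaussian_system <- function(model_kind = "hexagon",
                            peaks = if (model_kind == "hexagon")
                              c(350, 440, 540) else c(330, 450, 350, 530),
                            sigma = 30,
                            illuminant = NULL, background = NULL,
                            wavelengths = 300:700) {
  s <- sapply(peaks, function(p) exp(-((wavelengths - p) / sigma)^2 / 2))
  colnames(s) <- if (model_kind == "hexagon") c("UV", "B", "G") else
    c("R7p", "R8p", "R7y", "R8y")
  receptor_system(s,
                  illuminant %||% rep(1, length(wavelengths)),
                  background %||% rep(25, length(wavelengths)),
                  model_kind, wavelengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fine-grid (0.1 nm) trapezoid quantum-catch oracle for smooth analytic
# curves supplied as functions of wavelength.
qc_oracle <- function(s_fun, refl_fun, illum_fun, bg_fun,
                      lo = 300, hi = 700, step = 0.1) {
  wl <- seq(lo, hi, by = step)
  tz <- function(y) sum(diff(wl) * (y[-1] + y[-length(y)])) / 2
  tz(s_fun(wl) * illum_fun(wl) * refl_fun(wl)) /
    tz(s_fun(wl) * illum_fun(wl) * bg_fun(wl))
}

# Exhaustive enumeration of non-negative integer tables with fixed margins,
# and the brute-force H2' derived from their entropy extremes.
enum_margin_tables <- function(rs, cs) {
  out <- list()
  comp <- function(total, bounds) {
    if (length(bounds) == 1) {
      if (total <= bounds) return(list(total)) else return(list())
    }
    res <- list()
    for (v in 0:min(total, bounds[1])) {
      for (tail in comp(total - v, bounds[-1])) {
        res[[length(res) + 1]] <- c(v, tail)
      }
    }
    res
  }
  rec <- function(rows_left, cs_left, acc) {
    if (length(rows_left) == 0) {
      if (all(cs_left == 0)) out[[length(out) + 1]] <<- do.call(rbind, acc)
      return(invisible())
    }
    for (row in comp(rows_left[1], cs_left)) {
      rec(rows_left[-1], cs_left - row, c(acc, list(row)))
    }
  }
  rec(rs, cs, list())
  out
}

shannon_entropy <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

h2_prime_bruteforce <- function(m) {
  hs <- vapply(enum_margin_tables(rowSums(m), colSums(m)), shannon_entropy,
               numeric(1))
  if (max(hs) - min(hs) < 1e-12) return(0)
  min(1, max(0, (max(hs) - shannon_entropy(m)) / (max(hs) - min(hs))))
}

# Minimal three-ecotype fixture for barrier-table structure tests.
tiny_ranges <- function() {
  mk <- function(cells) {
    v <- matrix(0, 6, 6)
    v[cells] <- 1
    env_grid(v, xll = 0, yll = 0, cellsize = 1000)
  }
  list(a = mk(1:12), b = mk(7:18), c = mk(25:30))
}
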