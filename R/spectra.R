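#' Uniform wavenumber grid
#'
#' Defines the abscissa shared by all spectra in an analysis: `n_points`
#' equally spaced wavenumbers between `start` and `stop` (cm^-1). The default
#' covers 300--1800 cm^-1 at 2 cm^-1 spacing, the working range of a portable
#' 785 nm Raman spectrometer.
#'
#' @param start,stop Range limits in cm^-1; `start < stop`.
#' @param n_points Number of grid points (>= 2).
#' @return An object of class `wavenumber_grid`.
#' @examples
#' g <- wavenumber_grid()
#' head(grid_points(g))
#' @export
wavenumber_grid <- function(start = 300, stop = 1800, n_points = 751) {
  if (!is.numeric(start) || !is.numeric(stop) || start >= stop)
    stop("wavenumber_grid: need start < stop")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    stop("wavenumber_grid: n_points must be >= 2")
  structure(list(start = as.numeric(start), stop = as.numeric(stop),
                 n_points = n_points),
            class = "wavenumber_grid")
}

#' @rdname wavenumber_grid
#' @param grid A `wavenumber_grid`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  seq(grid$start, grid$stop, length.out = grid$n_points)
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g-%g cm^-1, %d points (%.4g cm^-1 spacing)\n",
              x$start, x$stop, x$n_points,
              (x$stop - x$start) / (x$n_points - 1)))
  invisible(x)
}

#' Raman spectrum
#'
#' A single SERS/Raman spectrum: one intensity value (arbitrary units) per
#' point of a [wavenumber_grid()], with optional mixture-class label and
#' sample/replicate identifiers.
#'
#' @param intensities Numeric vector of finite intensities, one per grid point.
#' @param grid A [wavenumber_grid()].
#' @param label Optional mixture-class label (e.g. `"BaP+Pyr"`).
#' @param sample_id,replicate_id Optional identifiers.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(intensities, grid = wavenumber_grid(),
                           label = NA_character_,
                           sample_id = NA_character_,
                           replicate_id = NA_character_) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop(sprintf("raman_spectrum: %d intensities for a %d-point grid",
                 length(intensities), grid$n_points))
  if (!all(is.finite(intensities)))
    stop("raman_spectrum: intensities must be finite")
  structure(list(grid = grid, intensities = intensities,
                 label = as.character(label),
                 sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> %d points, %g-%g cm^-1 | label=%s sample=%s rep=%s\n",
    x$grid$n_points, x$grid$start, x$grid$stop,
    x$label, x$sample_id, x$replicate_id))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  plot(grid_points(x$grid), x$intensities, type = "l",
       xlab = expression(Wavenumber ~ (cm^-1)),
       ylab = "Intensity (a.u.)", ...)
  invisible(x)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation of intensities onto `target`; wavenumbers outside the
#' source range take the nearest edge value. Used to bring spectra from
#' heterogeneous instruments onto the fixed-length input vector the networks
#' require.
#'
#' @param spectrum A [raman_spectrum()].
#' @param target A [wavenumber_grid()].
#' @return A [raman_spectrum()] on `target` with metadata preserved.
#' @export
resample_spectrum <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(target, "wavenumber_grid"))
  src <- spectrum$grid
  if (src$stop < target$start || src$start > target$stop)
    stop("resample_spectrum: source and target grids do not overlap")
  y <- stats::approx(grid_points(src), spectrum$intensities,
                     xout = grid_points(target), method = "linear",
                     rule = 2)$y
  raman_spectrum(y, target, label = spectrum$label,
                 sample_id = spectrum$sample_id,
                 replicate_id = spectrum$replicate_id)
}

#' Normalize spectrum intensities
#'
#' `minmax` maps intensities onto \[0, 1\]; `vector` scales to unit Euclidean
#' norm; `none` returns the spectrum unchanged. Per-spectrum min-max is the
#' default network input scaling: it removes the replicate-to-replicate scale
#' factor so classification rests on the peak pattern.
#'
#' @param spectrum A [raman_spectrum()].
#' @param method One of `"minmax"`, `"vector"`, `"none"`.
#' @return A [raman_spectrum()].
#' @export
normalize_spectrum <- function(spectrum, method = c("minmax", "vector", "none")) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  method <- match.arg(method)
  y <- spectrum$intensities
  if (method == "none") return(spectrum)
  if (diff(range(y)) < .Machine$double.eps * max(1, abs(y[1])))
    stop("normalize_spectrum: degenerate (constant) spectrum")
  y <- switch(method,
    minmax = (y - min(y)) / (max(y) - min(y)),
    vector = y / sqrt(sum(y^2)))
  out <- spectrum
  out$intensities <- y
  out
}

#' Peak query window
#'
#' A characteristic-peak lookup: band center and search half-width, both in
#' cm^-1.
#'
#' @param center Peak position in cm^-1.
#' @param half_width Half-width of the search window in cm^-1 (> 0).
#' @return An object of class `peak_query`.
#' @export
peak_query <- function(center, half_width = 10) {
  if (!is.numeric(center) || !is.numeric(half_width) || half_width <= 0)
    stop("peak_query: need numeric center and half_width > 0")
  structure(list(center = center, half_width = half_width),
            class = "peak_query")
}

#' Characteristic-peak intensity
#'
#' Maximum raw (baseline-uncorrected) intensity within
#' `[center - half_width, center + half_width]` cm^-1 — the statistic used to
#' follow a characteristic band across concentrations and replicates.
#'
#' @param spectrum A [raman_spectrum()].
#' @param center Peak position in cm^-1, or a [peak_query()].
#' @param half_width Half-width of the search window in cm^-1 (> 0);
#'   ignored when `center` is a [peak_query()].
#' @return Peak intensity (arbitrary units).
#' @export
peak_intensity <- function(spectrum, center, half_width = 10) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (inherits(center, "peak_query")) {
    half_width <- center$half_width
    center <- center$center
  }
  if (!is.numeric(half_width) || half_width <= 0)
    stop("peak_intensity: half_width must be > 0")
  g <- spectrum$grid
  if (center - half_width < g$start || center + half_width > g$stop)
    stop(sprintf(
      "peak_intensity: window [%g, %g] outside grid [%g, %g]",
      center - half_width, center + half_width, g$start, g$stop))
  wn <- grid_points(g)
  sel <- wn >= center - half_width & wn <= center + half_width
  max(spectrum$intensities[sel])
}

#' Relative standard deviation (RSD)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation — the
#' substrate-stability statistic computed over replicate characteristic-peak
#' intensities.
#'
#' @param values Numeric vector of at least two intensities with nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 3))  # sd = sqrt(2), mean = 2 -> 70.71
#' @export
rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("rsd: need at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps)
    stop("rsd: mean is zero")
  100 * stats::sd(values) / m
}
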