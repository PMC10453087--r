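#' Analyte peak library
#'
#' Characteristic Raman bands of one analyte: peak centers (cm^-1), relative
#' amplitudes in (0, 1], and full widths at half maximum (cm^-1).
#'
#' @param analyte Analyte name.
#' @param centers Peak centers in cm^-1 (inside 300--1800).
#' @param amplitudes Relative amplitudes in (0, 1].
#' @param fwhm Full widths at half maximum in cm^-1 (recycled).
#' @return An object of class `analyte_peaks`.
#' @export
analyte_peaks <- function(analyte, centers, amplitudes, fwhm = 10) {
  stopifnot(is.character(analyte), length(analyte) == 1)
  centers <- as.numeric(centers)
  amplitudes <- as.numeric(amplitudes)
  fwhm <- rep_len(as.numeric(fwhm), length(centers))
  if (length(centers) != length(amplitudes))
    stop("analyte_peaks: centers and amplitudes differ in length")
  if (any(centers < 300 | centers > 1800))
    stop("analyte_peaks: peak centers must lie in 300-1800 cm^-1")
  if (any(amplitudes <= 0 | amplitudes > 1))
    stop("analyte_peaks: amplitudes must be in (0, 1]")
  if (any(fwhm <= 0))
    stop("analyte_peaks: FWHM must be > 0")
  structure(list(analyte = analyte, centers = centers,
                 amplitudes = amplitudes, fwhm = fwhm),
            class = "analyte_peaks")
}

#' Default PAH peak library
#'
#' Characteristic SERS bands of the three target PAHs: benzo(a)pyrene (BaP)
#' at 524, 607, 1231 and 1376 cm^-1 with 607 strongest; naphthalene (Nap) at
#' 505 and 1372 cm^-1 with 1372 strongest; pyrene (Pyr) at 587, 1233 and
#' 1399 cm^-1 with 587 strongest. Nap amplitudes carry an overall 0.6x scale:
#' the C-C vibrations of Nap give weaker SERS response than the C-H modes of
#' BaP and Pyr.
#'
#' @return Named list of [analyte_peaks()] for `BaP`, `Nap`, `Pyr`.
#' @export
pah_peak_library <- function() {
  list(
    BaP = analyte_peaks("BaP",
                        centers = c(524, 607, 1231, 1376),
                        amplitudes = c(0.55, 1.00, 0.50, 0.70)),
    Nap = analyte_peaks("Nap",
                        centers = c(505, 1372),
                        amplitudes = 0.6 * c(0.42, 1.00)),
    Pyr = analyte_peaks("Pyr",
                        centers = c(587, 1233, 1399),
                        amplitudes = c(1.00, 0.60, 0.70)))
}

#' Unit-height Lorentzian line shape
#'
#' @param x Wavenumbers (cm^-1).
#' @param center Peak center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1).
#' @return Values in (0, 1], equal to 1 at `center`.
#' @export
lorentzian <- function(x, center, fwhm) {
  g <- (fwhm / 2)^2
  g / ((x - center)^2 + g)
}

#' Synthetic-dataset generator configuration
#'
#' Defaults encode the study design the generator emulates: four mixture
#' classes (BaP+Pyr, BaP+Nap, Pyr+Nap, BaP+Pyr+Nap), 20 samples per class,
#' 5 replicate spectra per sample (400 spectra total), per-analyte
#' concentrations drawn from the ladder 10, 8, 5, 2.5, 1, 0.5, 0.1,
#' 0.05 ug/mL. Signal amplitudes follow a Langmuir-type competitive
#' adsorption law (half-saturation `K`, competition strengths `alpha`);
#' spectra carry a broad fluorescence hump plus slight linear tilt, additive
#' Gaussian noise, and a log-normal per-replicate intensity factor calibrated
#' so characteristic-peak RSD stays below 10%.
#'
#' @param peak_library Named list of [analyte_peaks()].
#' @param grid [wavenumber_grid()] for generated spectra.
#' @param conc_ladder Concentration ladder in ug/mL.
#' @param K Langmuir half-saturation constant in ug/mL (> 0).
#' @param alpha Named competition strengths per analyte (>= 0).
#' @param baseline_amplitude Fluorescence hump height as a fraction of the
#'   saturating analyte signal (set 0 to disable the whole baseline).
#' @param baseline_center,baseline_fwhm Hump position/width in cm^-1.
#' @param baseline_tilt Linear tilt amplitude (high at the low-wavenumber
#'   edge, 0 at the high edge).
#' @param noise_sd Additive Gaussian noise standard deviation (signal units).
#' @param replicate_log_sd Log-scale sd of the per-spectrum replicate factor.
#' @param replicates_per_sample,samples_per_class Design sizes.
#' @param classes Named list mapping class label to constituent analytes.
#' @param conc_design Joint concentration design of a mixture sample:
#'   `"shared"` (default) gives every constituent the same ladder level,
#'   cycling through the ladder over the samples of a class so the stated
#'   10--0.05 ug/mL range is covered; `"independent"` draws each
#'   constituent's concentration independently from the ladder. The shared
#'   design matches mixtures prepared at a common concentration, where
#'   competitive adsorption redistributes — but does not extinguish — each
#'   constituent's signal; under independent draws a trace constituent next
#'   to saturating competitors is physically undetectable and class
#'   membership becomes partly unidentifiable.
#' @param seed Default seed used by [generate_dataset()] when none is given.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(peak_library = pah_peak_library(),
                             grid = wavenumber_grid(),
                             conc_ladder = c(10, 8, 5, 2.5, 1, 0.5, 0.1, 0.05),
                             K = 1,
                             alpha = c(BaP = 1, Nap = 1, Pyr = 1),
                             baseline_amplitude = 0.1,
                             baseline_center = 1300,
                             baseline_fwhm = 900,
                             baseline_tilt = 0.02,
                             noise_sd = 0.01,
                             replicate_log_sd = 0.08,
                             replicates_per_sample = 5,
                             samples_per_class = 20,
                             classes = list(
                               "BaP+Pyr" = c("BaP", "Pyr"),
                               "BaP+Nap" = c("BaP", "Nap"),
                               "Pyr+Nap" = c("Pyr", "Nap"),
                               "BaP+Pyr+Nap" = c("BaP", "Pyr", "Nap")),
                             conc_design = c("shared", "independent"),
                             seed = 1L) {
  conc_design <- match.arg(conc_design)
  stopifnot(inherits(grid, "wavenumber_grid"), is.list(peak_library))
  if (!all(vapply(peak_library, inherits, TRUE, "analyte_peaks")))
    stop("generator_config: peak_library entries must be analyte_peaks")
  if (K <= 0) stop("generator_config: K must be > 0")
  if (any(conc_ladder <= 0)) stop("generator_config: ladder must be positive")
  if (noise_sd < 0 || replicate_log_sd < 0 || baseline_amplitude < 0)
    stop("generator_config: noise scales must be >= 0")
  if (any(alpha < 0)) stop("generator_config: alpha must be >= 0")
  miss <- setdiff(unique(unlist(classes)), names(peak_library))
  if (length(miss))
    stop(sprintf("generator_config: classes use unknown analytes: %s",
                 paste(miss, collapse = ", ")))
  structure(list(peak_library = peak_library, grid = grid,
                 conc_ladder = as.numeric(conc_ladder), K = K, alpha = alpha,
                 baseline_amplitude = baseline_amplitude,
                 baseline_center = baseline_center,
                 baseline_fwhm = baseline_fwhm,
                 baseline_tilt = baseline_tilt,
                 noise_sd = noise_sd, replicate_log_sd = replicate_log_sd,
                 replicates_per_sample = as.integer(replicates_per_sample),
                 samples_per_class = as.integer(samples_per_class),
                 classes = classes, conc_design = conc_design, seed = seed),
            class = "generator_config")
}

#' Langmuir-type signal amplitude with competitive adsorption
#'
#' Fraction of substrate binding sites occupied by an analyte at
#' concentration `concentration` in the presence of competitors:
#' `c / (K + c + sum(alpha_j * c_j))`. The amplitude is 0 for an absent
#' analyte, saturates towards 1 at high concentration, increases in `c`
#' and decreases in every competitor load.
#'
#' @param concentration Analyte concentration (ug/mL, >= 0).
#' @param competitor_load Competitor concentrations (ug/mL, >= 0; vector).
#' @param K Half-saturation constant (ug/mL).
#' @param alpha Competition strengths, recycled over `competitor_load`.
#' @return Dimensionless amplitude in \[0, 1).
#' @export
signal_amplitude <- function(concentration, competitor_load = 0, K = 1,
                             alpha = 1) {
  if (any(concentration < 0))
    stop("signal_amplitude: concentration must be >= 0")
  if (any(competitor_load < 0))
    stop("signal_amplitude: competitor load must be >= 0")
  alpha <- rep_len(alpha, length(competitor_load))
  concentration / (K + concentration + sum(alpha * competitor_load))
}

.baseline_curve <- function(config) {
  wn <- grid_points(config$grid)
  if (config$baseline_amplitude <= 0) return(numeric(config$grid$n_points))
  hump <- config$baseline_amplitude *
    exp(-(wn - config$baseline_center)^2 /
          (2 * (config$baseline_fwhm / 2.35482)^2))
  tilt <- config$baseline_tilt * (config$grid$stop - wn) /
    (config$grid$stop - config$grid$start)
  hump + tilt
}

.clean_signal <- function(concentrations, config) {
  wn <- grid_points(config$grid)
  sig <- numeric(length(wn))
  nms <- names(concentrations)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("generate_spectrum: concentrations must be a named vector")
  unknown <- setdiff(nms, names(config$peak_library))
  if (length(unknown))
    stop(sprintf("generate_spectrum: unknown analyte(s): %s",
                 paste(unknown, collapse = ", ")))
  for (an in nms) {
    conc <- concentrations[[an]]
    if (conc <= 0) next
    others <- setdiff(nms, an)
    comp <- if (length(others)) unlist(concentrations[others]) else 0
    a_comp <- if (length(others)) config$alpha[others] else 1
    amp <- signal_amplitude(conc, comp, K = config$K, alpha = a_comp)
    pk <- config$peak_library[[an]]
    for (i in seq_along(pk$centers))
      sig <- sig + amp * pk$amplitudes[i] *
        lorentzian(wn, pk$centers[i], pk$fwhm[i])
  }
  sig
}

#' Generate one synthetic SERS spectrum
#'
#' Intensity model:
#' `I(nu) = r * sum_analytes amp * sum_peaks relamp * L(nu; center, FWHM)
#'  + baseline(nu) + eps(nu)`, clipped at 0, where `amp` is the competitive
#' Langmuir amplitude ([signal_amplitude()]), `r` a per-spectrum log-normal
#' replicate factor with median 1, and `eps` i.i.d. Gaussian noise.
#'
#' @param concentrations Named per-analyte concentrations in ug/mL
#'   (zero or absent analytes contribute nothing).
#' @param config A [generator_config()].
#' @param seed Optional integer; when given, output is a pure function of
#'   `(concentrations, config, seed)`.
#' @param label,sample_id,replicate_id Metadata passed to the spectrum.
#' @return A [raman_spectrum()].
#' @export
generate_spectrum <- function(concentrations, config = generator_config(),
                              seed = NULL, label = NA_character_,
                              sample_id = NA_character_,
                              replicate_id = NA_character_) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  sig <- .clean_signal(concentrations, config)
  r <- if (config$replicate_log_sd > 0)
    stats::rlnorm(1, 0, config$replicate_log_sd) else 1
  y <- r * sig + .baseline_curve(config)
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  raman_spectrum(pmax(y, 0), config$grid, label = label,
                 sample_id = sample_id, replicate_id = replicate_id)
}

#' Replicate spectra of one sample
#'
#' `n` spectra of the same analyte concentrations differing only in the
#' replicate intensity factor and noise draws — the replicate series used to
#' assess substrate stability via [rsd()] of characteristic-peak intensities.
#'
#' @inheritParams generate_spectrum
#' @param n Number of replicates (>= 2).
#' @return List of `n` [raman_spectrum()] objects.
#' @export
replicate_series <- function(concentrations, n, config = generator_config(),
                             seed = NULL, sample_id = "S1",
                             label = NA_character_) {
  if (n < 2) stop("replicate_series: need n >= 2 replicates")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    generate_spectrum(concentrations, config, label = label,
                      sample_id = sample_id,
                      replicate_id = as.character(i)))
}

#' Generate the full synthetic mixture dataset
#'
#' For each mixture class, `samples_per_class` samples with per-analyte
#' concentrations assigned per the config's `conc_design` — by default one
#' shared ladder level per sample, cycled through the ladder so each class
#' covers the full 10--0.05 ug/mL range — each sample measured
#' `replicates_per_sample` times. Defaults produce 400 spectra, 100 per
#' class. The result carries a manifest attribute recording seed and
#' configuration hash.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Object of class `sers_dataset`: list of `mixture_sample`s, each
#'   with `sample_id`, `class`, named `concentrations`, and `spectra`.
#' @export
generate_dataset <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (length(config$conc_ladder) == 0)
    stop("generate_dataset: empty concentration ladder")
  if (config$samples_per_class < 1 || config$replicates_per_sample < 1)
    stop("generate_dataset: need at least one sample and one replicate")
  set.seed(seed)
  analytes <- names(config$peak_library)
  samples <- list()
  shared <- is.null(config$conc_design) || config$conc_design == "shared"
  for (cls in names(config$classes)) {
    members <- config$classes[[cls]]
    levels_ <- rep(config$conc_ladder,
                   length.out = config$samples_per_class)
    for (s in seq_len(config$samples_per_class)) {
      conc <- stats::setNames(numeric(length(analytes)), analytes)
      conc[members] <- if (shared) levels_[s]
        else sample(config$conc_ladder, length(members), replace = TRUE)
      sid <- sprintf("%s_S%02d", gsub("\\+", "", cls), s)
      spectra <- lapply(seq_len(config$replicates_per_sample), function(r)
        generate_spectrum(conc[members],
                          config, label = cls, sample_id = sid,
                          replicate_id = as.character(r)))
      samples[[sid]] <- structure(
        list(sample_id = sid, class = cls, concentrations = conc,
             spectra = spectra),
        class = "mixture_sample")
    }
  }
  structure(samples, class = "sers_dataset",
            manifest = list(seed = as.integer(seed),
                            config_hash = config_hash(config),
                            classes = names(config$classes),
                            n_spectra = length(samples) *
                              config$replicates_per_sample))
}

#' Flatten a dataset (or spectrum list) into a design matrix
#'
#' @param x A `sers_dataset` from [generate_dataset()] or a list of
#'   [raman_spectrum()] objects sharing one grid.
#' @return List with `x` (spectra-by-wavenumber intensity matrix), `labels`
#'   (factor), `sample_id`, `replicate_id`, and `grid`.
#' @export
dataset_matrix <- function(x) {
  spectra <- if (inherits(x, "sers_dataset"))
    unlist(lapply(x, `[[`, "spectra"), recursive = FALSE)
  else x
  stopifnot(length(spectra) > 0,
            all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
  n_pts <- vapply(spectra, function(s) s$grid$n_points, 1L)
  if (length(unique(n_pts)) != 1)
    stop("dataset_matrix: spectra lie on different grids; resample first")
  m <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  list(x = m,
       labels = factor(vapply(spectra, `[[`, "", "label")),
       sample_id = vapply(spectra, `[[`, "", "sample_id"),
       replicate_id = vapply(spectra, `[[`, "", "replicate_id"),
       grid = spectra[[1]]$grid)
}

#' @export
print.sers_dataset <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "class")
  reps <- vapply(x, function(s) length(s$spectra), 1L)
  cat(sprintf("<sers_dataset> %d samples, %d spectra\n", length(x), sum(reps)))
  print(table(class = cls))
  invisible(x)
}
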