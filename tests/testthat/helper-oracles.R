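# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately written from first principles, without
# calling the package functions it is used to check.

# pointwise linear interpolation with edge clamping
lin_interp_oracle <- function(x, y, xout) {
  vapply(xout, function(x0) {
    if (x0 <= x[1]) return(y[1])
    if (x0 >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= x0))
    if (x[i] == x0) return(y[i])
    w <- (x0 - x[i]) / (x[i + 1] - x[i])
    (1 - w) * y[i] + w * y[i + 1]
  }, numeric(1))
}

# channel shuffle as an explicit reshape-(g, C/g)-transpose-flatten on
# indices: rows of m are the groups; a row-major flatten of t(m) is a
# column-major read of m itself
shuffle_perm_oracle <- function(C, g) {
  m <- matrix(seq_len(C), nrow = g, byrow = TRUE)
  as.integer(m)
}

# Lorentzian used by the generator, written independently
lorentz_oracle <- function(x, center, fwhm) {
  (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
}

# clean generator signal + baseline at given wavenumbers, from the model
# formulas (used by the Monte-Carlo RSD oracle)
clean_signal_oracle <- function(wn, conc, cfg) {
  sig <- numeric(length(wn))
  for (an in names(conc)) {
    if (conc[[an]] <= 0) next
    others <- setdiff(names(conc), an)
    load <- if (length(others)) sum(cfg$alpha[others] * unlist(conc[others]))
      else 0
    amp <- conc[[an]] / (cfg$K + conc[[an]] + load)
    pk <- cfg$peak_library[[an]]
    for (i in seq_along(pk$centers))
      sig <- sig + amp * pk$amplitudes[i] *
        lorentz_oracle(wn, pk$centers[i], pk$fwhm[i])
  }
  base <- cfg$baseline_amplitude *
    exp(-(wn - cfg$baseline_center)^2 / (2 * (cfg$baseline_fwhm / 2.35482)^2)) +
    cfg$baseline_tilt * (cfg$grid$stop - wn) / (cfg$grid$stop - cfg$grid$start)
  sig + base
}

# a small, cleanly separable labelled dataset: n_per_class samples per class
# on a coarse grid, noiseless unless noise_sd > 0
toy_spectra <- function(n_per_class = 1, n_points = 101, noise_sd = 0,
                        seed = 1) {
  cfg <- generator_config(grid = wavenumber_grid(300, 1800, n_points),
                          noise_sd = noise_sd, replicate_log_sd = 0,
                          baseline_amplitude = 0, baseline_tilt = 0,
                          samples_per_class = n_per_class,
                          replicates_per_sample = 1,
                          seed = seed)
  generate_dataset(cfg, seed = seed)
}

# a split object covering given indices without using split_dataset()
manual_split <- function(training, validation = training,
                         prediction = training, seed = 0) {
  structure(list(training = training, validation = validation,
                 prediction = prediction, seed = seed),
            class = "sersnet_split")
}

# the paper-scale Precision/Recall/F1 triples used as worked examples
table1_triples <- data.frame(
  precision = c(96.97, 93.75, 86.21, 100, 96.88, 100, 100, 89.66, 100),
  recall    = c(84.21, 96.77, 100, 93.94, 100, 86.84, 91.67, 100, 100),
  f1        = c(90.14, 95.24, 92.59, 96.88, 98.42, 92.96, 95.65, 94.55, 100))
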