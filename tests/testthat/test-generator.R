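test_that("competitive Langmuir amplitude behaves as a binding isotherm", {
  expect_equal(signal_amplitude(0, 0, K = 1), 0)
  expect_equal(signal_amplitude(1, 0, K = 1), 0.5)   # half saturation at c = K
  expect_equal(signal_amplitude(1e9, 0, K = 1), 1, tolerance = 1e-6)
  expect_error(signal_amplitude(-1), ">= 0")
  expect_error(signal_amplitude(1, -2), ">= 0")

  # strictly increasing in c, strictly decreasing in competitor load
  cs <- c(0.05, 0.1, 0.5, 1, 2.5, 5, 8, 10)
  amps <- vapply(cs, signal_amplitude, 1, competitor_load = 2)
  expect_true(all(diff(amps) > 0))
  comp <- vapply(cs, function(cl) signal_amplitude(5, cl), 1)
  expect_true(all(diff(comp) < 0))
})

test_that("generate_spectrum places peaks where the analyte library says", {
  quiet <- generator_config(noise_sd = 0, replicate_log_sd = 0,
                            baseline_amplitude = 0, baseline_tilt = 0)
  blank <- generate_spectrum(c(BaP = 0, Nap = 0, Pyr = 0), quiet)
  expect_true(all(blank$intensities == 0))

  bap <- generate_spectrum(c(BaP = 10), quiet)
  y <- bap$intensities
  wn <- grid_points(quiet$grid)
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  found <- sort(wn[is_max & y > 0.01 * max(y)])
  centers <- c(524, 607, 1231, 1376)
  spacing <- diff(wn)[1]
  # exactly one local maximum per library band, each within one grid step
  # of its center (a center midway between grid points can tip either way)
  expect_length(found, length(centers))
  expect_true(all(abs(found - centers) <= spacing))

  expect_error(generate_spectrum(c(Benzene = 1), quiet), "unknown analyte")

  # determinism given the rng seed
  cfg <- generator_config()
  expect_identical(generate_spectrum(c(BaP = 5, Nap = 1), cfg, seed = 33),
                   generate_spectrum(c(BaP = 5, Nap = 1), cfg, seed = 33))

  # spectra are clipped at zero even with heavy noise
  noisy <- generator_config(noise_sd = 1)
  expect_true(all(generate_spectrum(c(BaP = 0.05), noisy,
                                    seed = 2)$intensities >= 0))
})

test_that("generate_dataset reproduces the 4 x 20 x 5 design", {
  ds <- generate_dataset(generator_config(), seed = 1)
  mat <- dataset_matrix(ds)
  expect_equal(nrow(mat$x), 400)
  expect_true(all(table(mat$labels) == 100))
  expect_equal(ncol(mat$x), 751)

  # constituent concentrations exactly match the class label
  for (s in ds) {
    members <- strsplit(s$class, "+", fixed = TRUE)[[1]]
    expect_equal(sort(names(s$concentrations)[s$concentrations > 0]),
                 sort(members))
  }

  tiny <- generate_dataset(generator_config(samples_per_class = 1,
                                            replicates_per_sample = 1),
                           seed = 1)
  expect_equal(nrow(dataset_matrix(tiny)$x), 4)

  expect_identical(generate_dataset(generator_config(), seed = 5),
                   generate_dataset(generator_config(), seed = 5))
  expect_error(generate_dataset(generator_config(conc_ladder = numeric(0))),
               "positive|empty")
  expect_error(generate_dataset(generator_config(samples_per_class = 0)),
               "at least one")
})

test_that("replicate series reproduce the stability envelope", {
  frozen <- generator_config(noise_sd = 0, replicate_log_sd = 0)
  reps <- replicate_series(c(BaP = 10), n = 3, frozen)
  expect_identical(reps[[1]]$intensities, reps[[2]]$intensities)
  expect_equal(rsd(vapply(reps, peak_intensity, 1, center = 607)), 0)
  expect_error(replicate_series(c(BaP = 10), n = 1, frozen), "n >= 2")

  # defaults, n = 10, strongest peak of each analyte: RSD < 10%
  cfg <- generator_config()
  strongest <- c(BaP = 607, Nap = 1372, Pyr = 587)
  for (an in names(strongest)) {
    series <- replicate_series(stats::setNames(10, an), n = 10, cfg,
                               seed = 10)
    r <- rsd(vapply(series, peak_intensity, 1, center = strongest[[an]]))
    expect_lt(r, 10)
    expect_gt(r, 0)
  }
})

test_that("replicate RSD agrees with a Monte-Carlo oracle of the noise model", {
  cfg <- generator_config()
  wn_all <- grid_points(cfg$grid)
  win <- wn_all[abs(wn_all - 607) <= 10]
  clean <- clean_signal_oracle(win, list(BaP = 10), cfg)
  set.seed(99)
  draws <- replicate(10000, {
    r <- rlnorm(1, 0, cfg$replicate_log_sd)
    sig <- r * (clean - clean_signal_oracle(win, list(BaP = 0), cfg)) +
      clean_signal_oracle(win, list(BaP = 0), cfg) +
      rnorm(length(win), 0, cfg$noise_sd)
    max(pmax(sig, 0))
  })
  oracle_rsd <- 100 * sd(draws) / mean(draws)

  series <- replicate_series(c(BaP = 10), n = 10, cfg, seed = 1)
  emp <- rsd(vapply(series, peak_intensity, 1, center = 607))
  expect_lt(abs(emp - oracle_rsd), 3)
})

test_that("peak intensities are monotone in concentration and competition", {
  quiet <- generator_config(noise_sd = 0, replicate_log_sd = 0)
  ladder <- sort(quiet$conc_ladder)
  at607 <- vapply(ladder, function(cc)
    peak_intensity(generate_spectrum(c(BaP = cc), quiet), 607), numeric(1))
  expect_true(all(diff(at607) > 0))

  # increasing competitor load suppresses the BaP peak
  suppressed <- vapply(ladder, function(cc)
    peak_intensity(generate_spectrum(c(BaP = 5, Pyr = cc), quiet), 607),
    numeric(1))
  expect_true(all(diff(suppressed) < 0))
})

test_that("class mean spectra contain exactly their constituents' bands", {
  quiet <- generator_config(noise_sd = 0, replicate_log_sd = 0,
                            baseline_amplitude = 0, baseline_tilt = 0)
  wn <- grid_points(quiet$grid)
  lib <- quiet$peak_library
  class_peaks <- lapply(quiet$classes, function(members)
    sort(unlist(lapply(lib[members], `[[`, "centers"))))

  n_found <- numeric(0)
  for (cls in names(quiet$classes)) {
    conc <- stats::setNames(rep(10, length(quiet$classes[[cls]])),
                            quiet$classes[[cls]])
    y <- generate_spectrum(conc, quiet)$intensities
    is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
    found <- wn[is_max & y > 0.01 * max(y)]
    # every detected band lies near a constituent band and every
    # constituent band has a detected local maximum nearby (bands closer
    # than the linewidth merge into one maximum)
    expect_true(all(vapply(found, function(f)
      min(abs(class_peaks[[cls]] - f)) <= 6, TRUE)), label = cls)
    expect_true(all(vapply(class_peaks[[cls]], function(p)
      min(abs(found - p)) <= 6, TRUE)), label = cls)
    n_found[cls] <- length(found)
  }
  # the ternary mixture shows strictly more bands than any binary one
  expect_true(all(n_found["BaP+Pyr+Nap"] >
                    n_found[c("BaP+Pyr", "BaP+Nap", "Pyr+Nap")]))
})
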