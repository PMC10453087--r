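#' Write spectra to CSV
#'
#' Long format, one row per grid point per spectrum, columns
#' `sample_id, replicate_id, label, wavenumber_cm1, intensity`, UTF-8 with
#' header. The inverse of [read_spectra()].
#'
#' @param spectra List of [raman_spectrum()] objects (possibly empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(is.list(spectra))
  if (length(spectra) == 0) {
    dt <- data.table::data.table(sample_id = character(),
                                 replicate_id = character(),
                                 label = character(),
                                 wavenumber_cm1 = numeric(),
                                 intensity = numeric())
  } else {
    dt <- data.table::rbindlist(lapply(spectra, function(s) {
      stopifnot(inherits(s, "raman_spectrum"))
      data.table::data.table(sample_id = s$sample_id,
                             replicate_id = s$replicate_id,
                             label = s$label,
                             wavenumber_cm1 = grid_points(s$grid),
                             intensity = s$intensities)
    }))
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

.long_cols <- c("sample_id", "replicate_id", "label", "wavenumber_cm1",
                "intensity")

#' Read spectra from CSV
#'
#' Accepts the long format written by [write_spectra()] and, as a convenience,
#' a wide matrix variant whose first column is the wavenumber and whose
#' remaining columns are one spectrum each (column name becomes the
#' `sample_id`). Each spectrum must sit on a strictly increasing, uniformly
#' spaced wavenumber axis; malformed records raise an error naming the
#' offending spectrum.
#'
#' @param path CSV file path.
#' @return List of [raman_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_spectra: file not found: %s", path))
  dt <- as.data.frame(data.table::fread(path))
  if (nrow(dt) == 0 && all(.long_cols %in% names(dt)))
    return(list())
  if (all(.long_cols %in% names(dt)))
    return(.read_long(dt))
  .read_wide(dt)
}

.check_axis <- function(wn, who) {
  if (length(wn) < 2)
    stop(sprintf("read_spectra: spectrum %s has fewer than 2 points", who))
  d <- diff(wn)
  if (any(d <= 0))
    stop(sprintf("read_spectra: non-monotone wavenumbers in spectrum %s", who))
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop(sprintf("read_spectra: non-uniform wavenumber spacing in spectrum %s",
                 who))
  wavenumber_grid(wn[1], wn[length(wn)], length(wn))
}

.read_long <- function(dt) {
  if (!is.numeric(dt$wavenumber_cm1) || !is.numeric(dt$intensity))
    stop("read_spectra: wavenumber_cm1/intensity must be numeric")
  key <- paste(dt$sample_id, dt$replicate_id, sep = "\r")
  groups <- split(seq_len(nrow(dt)), factor(key, levels = unique(key)))
  n_pts <- lengths(groups)
  if (length(unique(n_pts)) > 1) {
    bad <- names(groups)[which(n_pts != n_pts[1])[1]]
    stop(sprintf("read_spectra: point-count mismatch for spectrum %s",
                 gsub("\r", "/", bad)))
  }
  lapply(groups, function(idx) {
    rows <- dt[idx, ]
    who <- sprintf("%s/%s", rows$sample_id[1], rows$replicate_id[1])
    if (length(unique(rows$label)) > 1)
      stop(sprintf("read_spectra: conflicting labels for spectrum %s", who))
    grid <- .check_axis(rows$wavenumber_cm1, who)
    raman_spectrum(rows$intensity, grid, label = rows$label[1],
                   sample_id = rows$sample_id[1],
                   replicate_id = rows$replicate_id[1])
  })
}

.read_wide <- function(dt) {
  if (ncol(dt) < 2)
    stop("read_spectra: wide format needs a wavenumber column plus spectra")
  wn <- dt[[1]]
  if (!is.numeric(wn))
    stop("read_spectra: first wide-format column must be numeric wavenumbers")
  grid <- .check_axis(wn, names(dt)[1])
  lapply(names(dt)[-1], function(nm) {
    y <- dt[[nm]]
    if (!is.numeric(y))
      stop(sprintf("read_spectra: non-numeric intensities in column %s", nm))
    raman_spectrum(y, grid, sample_id = nm, replicate_id = "1")
  })
}

#' Write a dataset manifest
#'
#' JSON sidecar recording the data files, class names and generator
#' provenance (seed plus an MD5 hash of the resolved configuration) so any
#' dataset on disk can be traced back to the exact generator call.
#'
#' @param path Output JSON path.
#' @param files Character vector of data file paths (stored as given).
#' @param classes Character vector of class names.
#' @param seed Integer seed used for generation (or `NA`).
#' @param config A [generator_config()] or any serializable list.
#' @param counts Optional named vector of per-class spectrum counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, files, classes, seed, config, counts = NULL) {
  manifest <- list(
    package = "sersnet",
    version = as.character(utils::packageVersion("sersnet")),
    files = as.character(files),
    classes = as.character(classes),
    seed = if (is.null(seed) || is.na(seed)) NA_integer_ else as.integer(seed),
    config_hash = config_hash(config),
    counts = as.list(counts))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_manifest
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
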