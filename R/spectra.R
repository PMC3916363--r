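# Profile spectra and peak lists: Gaussian smoothing, threshold-centroid
# peak picking and base-peak normalization, mirroring the processing chain
# of MALDI QIT-TOF profile acquisitions (Gaussian smoothing; threshold-25%
# centroid detection; intensities scaled to the base peak as 100%).

#' Construct a profile spectrum
#'
#' @param mz Strictly increasing numeric vector of m/z values.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param replicate Optional replicate identifier.
#' @param spot Optional spot identifier.
#' @return An object of class `profile_spectrum`.
#' @export
profile_spectrum <- function(mz, intensity, replicate = NA, spot = NA) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 replicate = replicate, spot = spot),
            class = "profile_spectrum")
}

#' @export
print.profile_spectrum <- function(x, ...) {
  cat(sprintf("Profile spectrum: %d points, m/z %.2f-%.2f\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Construct a peak list
#'
#' @param mz Strictly increasing centroid m/z values.
#' @param intensity Apex heights.
#' @param area Peak areas (defaults to `intensity` when not available).
#' @param normalized Whether intensities are scaled to base peak = 100.
#' @return A `peak_list` data.frame with columns `mz`, `intensity`, `area`.
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0),
                      area = intensity, normalized = FALSE) {
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  structure(data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                       area = as.numeric(area)),
            class = c("peak_list", "data.frame"), normalized = normalized)
}

# resample onto a uniform grid by linear interpolation if needed
.uniform_grid <- function(spec) {
  d <- diff(spec$mz)
  if (length(d) == 0) return(spec)
  if (max(d) - min(d) < 1e-9 * mean(d)) return(spec)
  grid <- seq(min(spec$mz), max(spec$mz), by = stats::median(d))
  it <- stats::approx(spec$mz, spec$intensity, xout = grid, rule = 2)$y
  profile_spectrum(grid, it, spec$replicate, spec$spot)
}

#' Gaussian smoothing of a profile spectrum
#'
#' Convolves the intensity array with a normalized Gaussian kernel of the
#' given standard deviation (in Da), with edge reflection so that total ion
#' current is preserved. Non-uniform m/z grids are resampled by linear
#' interpolation first.
#'
#' @param spec A `profile_spectrum`.
#' @param sigma Kernel standard deviation in Da (> 0).
#' @return A smoothed `profile_spectrum`.
#' @export
smooth_spectrum <- function(spec, sigma) {
  stopifnot(inherits(spec, "profile_spectrum"))
  if (sigma <= 0) stop("sigma must be > 0")
  spec <- .uniform_grid(spec)
  n <- length(spec$mz)
  if (n < 3) return(spec)
  dx <- spec$mz[2] - spec$mz[1]
  half <- max(1L, min(n - 1L, ceiling(4 * sigma / dx)))
  kern <- stats::dnorm(seq(-half, half) * dx, sd = sigma)
  kern <- kern / sum(kern)
  # reflect edges so the kernel never runs off the support
  padded <- c(rev(spec$intensity[seq_len(half) + 1]),
              spec$intensity,
              rev(spec$intensity[n - seq_len(half)]))
  sm <- stats::convolve(padded, rev(kern), type = "filter")
  sm[sm < 0] <- 0  # clip FFT round-off below zero
  profile_spectrum(spec$mz, sm, spec$replicate, spec$spot)
}

#' Threshold-centroid peak detection
#'
#' Detects local maxima above an absolute intensity offset; for each apex,
#' the centroid m/z is the intensity-weighted mean over the contiguous
#' region where intensity >= `threshold_fraction` x apex height. Reported
#' intensity is the apex height; area is the trapezoidal integral of the
#' profile over that region. The defaults (25% threshold, offset 0.5
#' intensity units) mirror threshold-25% centroid detection with a 0.5
#' units threshold offset.
#'
#' @param spec A `profile_spectrum` (smoothing first is recommended).
#' @param threshold_fraction Fraction of the apex defining the centroid
#'   region, in (0, 1); default 0.25.
#' @param threshold_offset Absolute intensity floor for apex detection, in
#'   the spectrum's own intensity units; default 0.5.
#' @return A `peak_list`.
#' @export
centroid_spectrum <- function(spec, threshold_fraction = 0.25,
                              threshold_offset = 0.5) {
  stopifnot(inherits(spec, "profile_spectrum"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  y <- spec$intensity; x <- spec$mz; n <- length(y)
  if (n < 3) return(peak_list())
  is_apex <- which(y[-c(1, n)] >= y[-c(n - 1, n)] &
                   y[-c(1, n)] > y[-c(1, 2)] &
                   y[-c(1, n)] > threshold_offset) + 1L
  if (!length(is_apex)) return(peak_list())
  out_mz <- out_int <- out_area <- numeric(length(is_apex))
  kept <- logical(length(is_apex))
  for (j in seq_along(is_apex)) {
    i <- is_apex[j]
    thr <- threshold_fraction * y[i]
    lo <- i; while (lo > 1 && y[lo - 1] >= thr && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- i; while (hi < n && y[hi + 1] >= thr && y[hi + 1] <= y[hi]) hi <- hi + 1
    idx <- lo:hi
    out_mz[j] <- sum(x[idx] * y[idx]) / sum(y[idx])
    out_int[j] <- y[i]
    out_area[j] <- if (length(idx) > 1) pracma::trapz(x[idx], y[idx]) else 0
    kept[j] <- TRUE
  }
  out_mz <- out_mz[kept]; out_int <- out_int[kept]; out_area <- out_area[kept]
  # two apexes sharing a centroid region can produce duplicate centroids
  ord <- order(out_mz)
  out_mz <- out_mz[ord]; out_int <- out_int[ord]; out_area <- out_area[ord]
  dup <- c(FALSE, diff(out_mz) < 1e-9)
  peak_list(out_mz[!dup], out_int[!dup], out_area[!dup])
}

#' Base-peak normalization
#'
#' Scales a peak list so its most intense peak is exactly 100. Ratios
#' between peaks are unchanged, so downstream quantification is invariant
#' to this scaling. Idempotent.
#'
#' @param peaks A non-empty `peak_list`.
#' @return The normalized `peak_list`.
#' @export
normalize_base_peak <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  if (nrow(peaks) == 0) stop("cannot normalize an empty peak list")
  f <- 100 / max(peaks$intensity)
  peak_list(peaks$mz, peaks$intensity * f, peaks$area * f, normalized = TRUE)
}

#' Read a peak list from disk
#'
#' Two dialects: `"csv"` (columns `mz`, `intensity` and optionally `area`,
#' with header) and `"txt"` (two whitespace-separated numeric columns, no
#' header). Malformed rows raise an error naming the offending line.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"txt"`.
#' @return A `peak_list`.
#' @export
read_peaklist <- function(path, dialect = c("csv", "txt")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || (dialect == "csv" && length(lines) == 1))
    return(peak_list())
  if (dialect == "csv") {
    header <- gsub("\"", "", trimws(strsplit(lines[1], ",")[[1]]))
    body <- lines[-1]
    rows <- strsplit(body, ",")
    parse_row <- function(i) {
      vals <- suppressWarnings(as.numeric(trimws(rows[[i]])))
      if (anyNA(vals) || length(vals) != length(header))
        stop("malformed peak list row at line ", i + 1, ": ", body[i])
      stats::setNames(vals, trimws(header))
    }
    mat <- t(vapply(seq_along(rows), parse_row,
                    numeric(length(header))))
    mz <- mat[, "mz"]; it <- mat[, "intensity"]
    area <- if ("area" %in% colnames(mat)) mat[, "area"] else it
  } else {
    rows <- strsplit(trimws(lines), "[[:space:]]+")
    parse_row <- function(i) {
      vals <- suppressWarnings(as.numeric(rows[[i]]))
      if (anyNA(vals) || length(vals) != 2)
        stop("malformed peak list row at line ", i, ": ", lines[i])
      vals
    }
    mat <- t(vapply(seq_along(rows), parse_row, numeric(2)))
    mz <- mat[, 1]; it <- mat[, 2]; area <- it
  }
  ord <- order(mz)
  peak_list(mz[ord], it[ord], area[ord])
}

#' Write a peak list to disk
#'
#' @param peaks A `peak_list`.
#' @param path File path.
#' @param dialect `"csv"` or `"txt"` (see [read_peaklist()]).
#' @export
write_peaklist <- function(peaks, path, dialect = c("csv", "txt")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    utils::write.csv(as.data.frame(peaks)[c("mz", "intensity", "area")],
                     path, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(peaks)[c("mz", "intensity")], path,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a profile spectrum from an mzML file
#'
#' Thin convenience reader over the mzR parser for instrument-exported
#' mzML; the package's canonical interchange format remains the CSV peak
#' list / profile dialects.
#'
#' @param path mzML file path.
#' @param scan Scan number (default 1).
#' @return A `profile_spectrum`.
#' @export
read_mzml <- function(path, scan = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  pk <- mzR::peaks(h, scan)
  profile_spectrum(pk[, 1], pk[, 2])
}

#' Write a quantification table as CSV
#'
#' Writes the wide one-row-per-glycan table of a fitted quantification (see
#' [quantify_experiment()]); per-replicate ratios go to a companion
#' long-format file when `replicate_path` is given.
#'
#' @param fit A `glyco_quant` object or its `$table` data.frame.
#' @param path Output CSV path.
#' @param replicate_path Optional path for the long-format per-replicate
#'   ratio table.
#' @export
write_quant_table <- function(fit, path, replicate_path = NULL) {
  tab <- if (inherits(fit, "glyco_quant")) fit$table else fit
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(replicate_path) && inherits(fit, "glyco_quant"))
    utils::write.csv(fit$replicates, replicate_path, row.names = FALSE)
  invisible(path)
}
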