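# Light/heavy pairing and relative quantification: the core computation.
#
# For each assigned glycan, the light (amide-14N) and heavy (amide-15N)
# isotopic envelopes are paired; because the label shift is only
# labeled_nitrogens x 0.99703 Da, the heavy envelope of small-HexNAc
# glycans (shift ~2 Da) lands inside the light envelope's 13C isotopologues
# and the two clusters merge at unit resolution. The ratio estimator
# therefore models the observed cluster intensities as a non-negative
# linear combination of the two theoretical envelopes and reads the ratio
# off the fitted coefficients, rather than dividing monoisotopic heights.

#' Build the light/heavy envelope pair for a composition
#'
#' @param comp A `glycan_composition`.
#' @param ion An `ion_spec`; its `enrichment` is used for the heavy
#'   envelope. Default singly sodiated native, enrichment 1.0.
#' @param n_peaks Envelope length (default 10 aggregated peaks).
#' @return An object of class `labeled_pair`: the composition, light and
#'   heavy `isotopic_envelope`s on the ion m/z scale, `shift` (Da),
#'   `n_labeled`, and the analysis `window` (light monoisotopic - 1.5 Da to
#'   heavy envelope end + 1.5 Da).
#' @export
build_pair <- function(comp, ion = ion_spec(), n_peaks = 10L) {
  if (!is_valid_glycan(comp)) stop("invalid or empty glycan composition")
  f <- composition_formula(comp, ion$derivatization)
  nlab <- labeled_nitrogens(comp)
  light <- .envelope_as_ion(natural_envelope(f, n_peaks), ion)
  heavy <- .envelope_as_ion(
    labeled_envelope(f, nlab, enrichment = ion$enrichment, n_peaks = n_peaks),
    ion)
  structure(list(
    composition = comp,
    light = light, heavy = heavy,
    n_labeled = nlab,
    shift = nlab * .N15_SHIFT,
    window = c(min(light$mz) - 1.5, max(heavy$mz) + 1.5)
  ), class = "labeled_pair")
}

#' @export
print.labeled_pair <- function(x, ...) {
  cat(sprintf("Labeled pair %s: shift %.3f Da (%d labeled N), window %.2f-%.2f\n",
              composition_string(x$composition), x$shift, x$n_labeled,
              x$window[1], x$window[2]))
  invisible(x)
}

# Cluster the union of expected light/heavy isotopologue positions into
# unit-resolution bins. Positions closer than `gap` merge (light M+k and
# heavy M+(k-shift) differ by only a few mDa x k).
.pair_clusters <- function(pair, gap = 0.5) {
  pos <- c(pair$light$mz, pair$heavy$mz)
  lab <- rep(c("L", "H"), c(nrow(pair$light), nrow(pair$heavy)))
  ab <- c(pair$light$abundance, pair$heavy$abundance)
  ord <- order(pos)
  pos <- pos[ord]; lab <- lab[ord]; ab <- ab[ord]
  cl <- cumsum(c(1, diff(pos) > gap))
  k <- max(cl)
  centers <- vapply(seq_len(k), function(j) mean(pos[cl == j]), numeric(1))
  L <- vapply(seq_len(k), function(j) sum(ab[cl == j & lab == "L"]), numeric(1))
  H <- vapply(seq_len(k), function(j) sum(ab[cl == j & lab == "H"]), numeric(1))
  list(centers = centers, L = L, H = H)
}

# observed response per cluster: summed measure of peaks within tolerance
.cluster_response <- function(peaks, centers, tolerance, measure) {
  vals <- if (measure == "area" && any(peaks$area > 0)) peaks$area
          else peaks$intensity
  vapply(centers, function(cmz) {
    sum(vals[abs(peaks$mz - cmz) <= tolerance])
  }, numeric(1))
}

#' Fit the light/heavy amounts of one glycan pair
#'
#' Models the observed intensities at the expected isotopologue cluster
#' positions as `light_amount * L + heavy_amount * H`, where L and H are
#' the normalized theoretical envelopes, and solves the two-coefficient
#' non-negative least-squares problem. The ratio is
#' `light_amount / heavy_amount`. This envelope deconvolution matters
#' precisely when the label shift is small enough (<= ~4 Da) that the heavy
#' monoisotopic cluster also contains light 13C isotopologues.
#'
#' The `"monoisotopic"` estimator (naive height ratio of the two leading
#' clusters, no overlap correction) is provided for comparison; it is
#' biased downward for overlapping pairs because the heavy monoisotopic
#' cluster is contaminated by the light M+shift isotopologue.
#'
#' @param peaks A `peak_list` (centroided) or `profile_spectrum` (centroided
#'   internally with default parameters).
#' @param pair A `labeled_pair` from [build_pair()].
#' @param tolerance Peak-to-position match tolerance in Da (default 0.3).
#' @param estimator `"nnls"` (default, envelope deconvolution) or
#'   `"monoisotopic"`.
#' @param measure `"area"` (default) or `"intensity"` (apex height).
#' @param signal_floor Total-window signal below which the fit is flagged
#'   low-signal and no ratio is reported (default 0).
#' @return A list: `light_amount`, `heavy_amount`, `ratio` (NA when
#'   undefined), `residual` (fraction of cluster signal unexplained), and
#'   `flags` (character vector; may contain "low_signal",
#'   "undefined_ratio").
#' @export
fit_pair <- function(peaks, pair, tolerance = 0.3,
                     estimator = c("nnls", "monoisotopic"),
                     measure = c("area", "intensity"), signal_floor = 0) {
  estimator <- match.arg(estimator)
  measure <- match.arg(measure)
  if (inherits(peaks, "profile_spectrum"))
    peaks <- centroid_spectrum(smooth_spectrum(peaks, sigma = 0.05))
  cl <- .pair_clusters(pair)
  y <- .cluster_response(peaks, cl$centers, tolerance, measure)
  flags <- character(0)
  total <- sum(y)
  if (total <= signal_floor || total == 0) {
    return(list(light_amount = NA_real_, heavy_amount = NA_real_,
                ratio = NA_real_, residual = NA_real_,
                flags = "low_signal"))
  }
  if (estimator == "nnls") {
    A <- cbind(cl$L, cl$H)
    fit <- pracma::lsqnonneg(A, y)
    coefs <- fit$x
    resid_frac <- sum(abs(y - A %*% coefs)) / total
    light <- coefs[1]; heavy <- coefs[2]
  } else {
    # leading cluster of each envelope, no overlap correction
    i_l <- which.min(abs(cl$centers - pair$light$mz[1]))
    i_h <- which.min(abs(cl$centers - pair$heavy$mz[1]))
    light <- y[i_l] / pair$light$abundance[1]
    heavy <- y[i_h] / pair$heavy$abundance[1]
    resid_frac <- NA_real_
  }
  ratio <- if (heavy > 0) light / heavy else NA_real_
  if (heavy == 0) flags <- c(flags, "undefined_ratio")
  list(light_amount = light, heavy_amount = heavy, ratio = ratio,
       residual = resid_frac, flags = flags)
}

#' Aggregate per-replicate ratios into mean and CV%
#'
#' @param ratios Numeric vector of per-replicate ratios (NAs dropped).
#' @return A list: `mean`, `cv_pct` (100 x sample sd / mean; NA with a flag
#'   when fewer than 2 finite ratios are available), `n`, `flags`.
#' @export
aggregate_ratios <- function(ratios) {
  r <- ratios[is.finite(ratios)]
  if (length(r) == 0)
    return(list(mean = NA_real_, cv_pct = NA_real_, n = 0L,
                flags = "no_ratios"))
  if (length(r) == 1)
    return(list(mean = r, cv_pct = NA_real_, n = 1L, flags = "cv_unavailable"))
  m <- mean(r)
  list(mean = m, cv_pct = 100 * stats::sd(r) / m, n = length(r),
       flags = character(0))
}

#' Up/no/down change call from a mean ratio
#'
#' A glycan is called down-regulated when its mean light/heavy ratio falls
#' below `lower`, up-regulated above `upper`, unchanged otherwise
#' (boundaries inclusive of "no"). The defaults 0.83 and 1.20 are the
#' distinguishability thresholds justified by the replicate CVs staying
#' below 20%.
#'
#' @param mean_ratio Positive mean ratio (vectorized).
#' @param lower,upper Thresholds (defaults 0.83, 1.20).
#' @return Character vector in `c("up", "down", "no")`.
#' @export
change_call <- function(mean_ratio, lower = 0.83, upper = 1.20) {
  if (any(!is.na(mean_ratio) & mean_ratio <= 0))
    stop("mean_ratio must be positive")
  ifelse(is.na(mean_ratio), NA_character_,
         ifelse(mean_ratio < lower, "down",
                ifelse(mean_ratio > upper, "up", "no")))
}

#' Quantify a dual-labeled glycomics experiment
#'
#' The package's fitting function. For every assigned composition it builds
#' the light/heavy envelope pair, fits the per-replicate light/heavy
#' amounts by envelope deconvolution ([fit_pair()]), aggregates replicate
#' ratios into mean and CV%, annotates the glycan class and emits the
#' up/no/down change call. Rows are sorted by theoretical m/z.
#'
#' @param replicates A list of `peak_list` or `profile_spectrum` objects,
#'   one per replicate acquisition of the 1:1 light/heavy mixture.
#' @param compositions Character vector of composition strings or a list of
#'   `glycan_composition` objects (typically the assigned compositions from
#'   [match_peaks()]).
#' @param ion An `ion_spec` (adduct, derivatization, heavy-channel
#'   enrichment).
#' @param tolerance Peak match tolerance in Da.
#' @param estimator `"nnls"` or `"monoisotopic"` (see [fit_pair()]).
#' @param measure `"area"` or `"intensity"`.
#' @param lower,upper Change-call thresholds.
#' @param cv_gate CV% above which a record is QC-flagged (default 20).
#' @param curated Curated class map (default [curated_classes()]).
#' @param light_name,heavy_name Sample names of the two channels; recorded
#'   in the fit so the ratio orientation (light/heavy) is never implicit.
#' @return An object of class `glyco_quant` with components `table` (one
#'   row per glycan: composition, class, bisecting, theoretical m/z, mean
#'   ratio, CV%, n, change, QC flags), `replicates` (long-format
#'   per-replicate ratios), and `config` (the resolved settings). Methods:
#'   `print`, `summary`, `coef`, `plot`, `residuals`.
#' @export
quantify_experiment <- function(replicates, compositions, ion = ion_spec(),
                                tolerance = 0.3,
                                estimator = c("nnls", "monoisotopic"),
                                measure = c("area", "intensity"),
                                lower = 0.83, upper = 1.20, cv_gate = 20,
                                curated = curated_classes(),
                                light_name = "light", heavy_name = "heavy") {
  estimator <- match.arg(estimator)
  measure <- match.arg(measure)
  if (!length(replicates)) stop("at least one replicate is required")
  if (inherits(replicates, c("peak_list", "profile_spectrum")))
    replicates <- list(replicates)
  comps <- lapply(compositions, function(x) {
    if (inherits(x, "glycan_composition")) x else parse_glycan(x)
  })
  # centroid profile replicates once up front
  reps <- lapply(replicates, function(r) {
    if (inherits(r, "profile_spectrum"))
      centroid_spectrum(smooth_spectrum(r, sigma = 0.05))
    else r
  })
  rows <- list(); longs <- list()
  for (comp in comps) {
    pair <- build_pair(comp, ion)
    fits <- lapply(reps, fit_pair, pair = pair, tolerance = tolerance,
                   estimator = estimator, measure = measure)
    ratios <- vapply(fits, function(f) f$ratio, numeric(1))
    resid <- vapply(fits, function(f) {
      if (is.na(f$residual)) NA_real_ else f$residual
    }, numeric(1))
    agg <- aggregate_ratios(ratios)
    ann <- classify_glycan(comp, curated)
    flags <- unique(c(agg$flags, unlist(lapply(fits, `[[`, "flags"))))
    if (!is.na(agg$cv_pct) && agg$cv_pct > cv_gate)
      flags <- c(flags, "high_cv")
    if (any(!is.na(resid) & resid > 0.25)) flags <- c(flags, "high_residual")
    call <- if (is.na(agg$mean)) NA_character_
            else change_call(agg$mean, lower, upper)
    cs <- composition_string(comp)
    rows[[length(rows) + 1]] <- data.frame(
      composition = cs, glycan_class = ann$glycan_class,
      bisecting = ann$bisecting,
      theoretical_mz = composition_mass(comp, ion),
      mean_ratio = agg$mean, cv_pct = agg$cv_pct, n = agg$n,
      change = call, flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
    longs[[length(longs) + 1]] <- data.frame(
      composition = cs, replicate = seq_along(ratios), ratio = ratios,
      residual = resid, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$theoretical_mz)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    replicates = do.call(rbind, longs),
    config = list(ion = ion, tolerance = tolerance, estimator = estimator,
                  measure = measure, lower = lower, upper = upper,
                  cv_gate = cv_gate, light_name = light_name,
                  heavy_name = heavy_name, n_replicates = length(reps))
  ), class = "glyco_quant")
}

#' @export
print.glyco_quant <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf(
    "Dual-label glycan quantification: %d glycans, %d replicates (%s/%s ratios, %s estimator)\n",
    nrow(x$table), cfg$n_replicates, cfg$light_name, cfg$heavy_name,
    cfg$estimator))
  tab <- x$table
  tab$mean_ratio <- round(tab$mean_ratio, digits)
  tab$cv_pct <- round(tab$cv_pct, 1)
  tab$theoretical_mz <- round(tab$theoretical_mz, 1)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Class-level summary of a fitted quantification
#'
#' Per glycan class: glycan count, min/median/max mean ratio and the tally
#' of up/no/down calls, with the bisecting class (the headline glycoform
#' family) listed with its ratio range.
#'
#' @param object A `glyco_quant` fit.
#' @param ... Unused.
#' @return A `summary.glyco_quant` object (data.frame of class summaries
#'   plus attributes).
#' @export
summary.glyco_quant <- function(object, ...) {
  tab <- object$table
  tab <- tab[!is.na(tab$mean_ratio), , drop = FALSE]
  cls <- split(tab, tab$glycan_class)
  rows <- lapply(names(cls), function(nm) {
    g <- cls[[nm]]
    data.frame(glycan_class = nm, n = nrow(g),
               min_ratio = min(g$mean_ratio),
               median_ratio = stats::median(g$mean_ratio),
               max_ratio = max(g$mean_ratio),
               up = sum(g$change == "up", na.rm = TRUE),
               no = sum(g$change == "no", na.rm = TRUE),
               down = sum(g$change == "down", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("summary.glyco_quant", "data.frame"),
            n_total = nrow(object$table),
            bisecting = tab[tab$bisecting, , drop = FALSE])
}

#' @export
print.summary.glyco_quant <- function(x, ...) {
  cat("Glycan class summary (", attr(x, "n_total"), " glycans):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  b <- attr(x, "bisecting")
  if (nrow(b)) {
    cat(sprintf(
      "\nBisecting GlcNAc glycans: %d, ratios %.2f-%.2f, calls: %s\n",
      nrow(b), min(b$mean_ratio), max(b$mean_ratio),
      paste(sort(unique(b$change)), collapse = "/")))
  }
  invisible(x)
}

#' @export
coef.glyco_quant <- function(object, ...) {
  stats::setNames(object$table$mean_ratio, object$table$composition)
}

#' @export
residuals.glyco_quant <- function(object, ...) {
  object$replicates$residual
}

#' Plot a fitted quantification
#'
#' Mean light/heavy ratio (log scale) against theoretical m/z with the
#' change-call thresholds; bisecting-GlcNAc glycans are highlighted.
#'
#' @param x A `glyco_quant` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glyco_quant <- function(x, ...) {
  tab <- x$table[!is.na(x$table$mean_ratio), , drop = FALSE]
  col <- ifelse(tab$bisecting, "firebrick", "grey30")
  pch <- ifelse(tab$bisecting, 17, 19)
  graphics::plot(tab$theoretical_mz, tab$mean_ratio, log = "y", col = col,
                 pch = pch, xlab = "theoretical m/z [M+Na]+",
                 ylab = sprintf("ratio (%s/%s)", x$config$light_name,
                                x$config$heavy_name), ...)
  graphics::abline(h = c(x$config$lower, x$config$upper), lty = 2,
                   col = "grey60")
  graphics::legend("topright", legend = c("bisecting GlcNAc", "other"),
                   col = c("firebrick", "grey30"), pch = c(17, 19),
                   bty = "n")
  invisible(x)
}
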