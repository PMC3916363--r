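# Aggregated (unit-mass-binned) isotopic envelopes from elemental formulas,
# including partial 15N enrichment at the labeled amide-nitrogen positions.
#
# An envelope is represented on the integer "neutron shift" grid: bin k
# holds all isotopologues with k extra neutrons relative to the lightest
# species. Each bin carries its total probability and the abundance-weighted
# mean (centroid) mass of the isotopologues it aggregates, so successive
# bins are spaced by ~1.003 Da for CHNO analytes. This matches the ~unit
# resolution of a MALDI QIT-TOF, where fine structure is not resolved.

# internal envelope representation: list(p = probabilities by shift 0..K,
# m = centroid mass per bin). Convolution combines probabilities and tracks
# mass centroids exactly.
.env_convolve <- function(a, b, trunc = 1e-15) {
  na <- length(a$p); nb <- length(b$p)
  p <- numeric(na + nb - 1)
  pm <- numeric(na + nb - 1)  # probability-weighted mass accumulator
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    idx <- i + seq_len(nb) - 1
    w <- a$p[i] * b$p
    p[idx] <- p[idx] + w
    pm[idx] <- pm[idx] + w * (a$m[i] + b$m)
  }
  m <- ifelse(p > 0, pm / p, 0)
  keep <- max(which(p > trunc * max(p)))
  list(p = p[seq_len(keep)], m = m[seq_len(keep)])
}

.env_identity <- list(p = 1, m = 0)

# distribution of one atom of an element, optionally with overridden
# isotope abundances (used for enriched nitrogen)
.atom_dist <- function(element, abundance = NULL) {
  iso <- .ISOTOPES[[element]]
  if (is.null(iso)) stop("unknown element: ", element)
  ab <- if (is.null(abundance)) iso$abundance else abundance
  p <- numeric(max(iso$shift) + 1)
  m <- numeric(max(iso$shift) + 1)
  p[iso$shift + 1] <- ab
  m[iso$shift + 1] <- iso$mass
  list(p = p, m = m)
}

# n-fold self-convolution by binary exponentiation
.env_power <- function(d, n) {
  out <- .env_identity
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) out <- .env_convolve(out, base)
    base <- .env_convolve(base, base)
    n <- n %/% 2
  }
  out
}

.as_envelope <- function(env, n_peaks, meta = list()) {
  p <- env$p; m <- env$m
  keep <- min(n_peaks, length(p))
  # truncation mass must be negligible: extend if the tail still matters
  p <- p[seq_len(keep)]; m <- m[seq_len(keep)]
  s <- sum(p)
  structure(
    data.frame(mz = m, abundance = p / s),
    class = c("isotopic_envelope", "data.frame"),
    truncated_mass = 1 - s,
    meta = meta
  )
}

#' Natural-abundance isotopic envelope of a formula
#'
#' Computes the aggregated isotopologue distribution of a neutral elemental
#' formula by per-element binomial/multinomial expansion convolved across
#' elements. Peak m/z values are abundance-weighted centroids within each
#' nominal-mass bin; abundances are normalized to sum to 1 over the
#' returned peaks.
#'
#' @param formula An `elemental_formula` (non-empty).
#' @param n_peaks Number of leading aggregated peaks to return (default 10).
#' @return An `isotopic_envelope`: a data.frame with columns `mz` (neutral
#'   mass scale) and `abundance`, plus attributes `truncated_mass` and
#'   `meta`.
#' @export
natural_envelope <- function(formula, n_peaks = 10L) {
  if (!inherits(formula, "elemental_formula") || sum(formula) == 0)
    stop("non-empty elemental_formula required")
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  env <- .env_identity
  for (el in names(formula)) {
    if (formula[[el]] == 0) next
    env <- .env_convolve(env, .env_power(.atom_dist(el), formula[[el]]))
  }
  .as_envelope(env, n_peaks, meta = list(labeling = "natural"))
}

#' Isotopic envelope with enriched 15N at labeled positions
#'
#' The `n_labeled_n` labeled amide nitrogens follow a binomial 15N
#' distribution convolved with the natural-abundance envelope of all
#' remaining atoms. `enrichment` is the isotopic purity of the labeled
#' glutamine pool: a labeled position draws from that pool (pure 15N) with
#' probability `enrichment` and from the natural nitrogen pool otherwise,
#' so its effective 15N probability is
#' `enrichment + (1 - enrichment) * p15_natural`. Enrichment 0 therefore
#' reduces exactly to [natural_envelope()], and enrichment 1 shifts the
#' monoisotopic peak by `n_labeled_n` x 0.99703 Da.
#'
#' Note the returned envelope always starts at its lightest populated bin:
#' at intermediate enrichment the leading bins (all-14N species and
#' partially labeled satellites) carry small but nonzero abundance.
#'
#' @param formula An `elemental_formula`; must contain at least
#'   `n_labeled_n` nitrogen atoms.
#' @param n_labeled_n Number of labeled nitrogen positions.
#' @param enrichment Fraction 15N at each labeled position, in [0, 1].
#' @param n_peaks Number of leading aggregated peaks to return.
#' @return An `isotopic_envelope` (see [natural_envelope()]).
#' @export
labeled_envelope <- function(formula, n_labeled_n, enrichment = 1.0,
                             n_peaks = 10L) {
  if (!inherits(formula, "elemental_formula") || sum(formula) == 0)
    stop("non-empty elemental_formula required")
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  n_total <- formula_nitrogens(formula)
  if (n_labeled_n < 0 || n_labeled_n > n_total)
    stop("n_labeled_n exceeds nitrogen count of formula")
  env <- .env_identity
  for (el in names(formula)) {
    k <- formula[[el]]
    if (el == "N") k <- k - n_labeled_n
    if (k == 0) next
    env <- .env_convolve(env, .env_power(.atom_dist(el), k))
  }
  if (n_labeled_n > 0) {
    # impurity of the labeled pool carries natural nitrogen
    p15 <- enrichment + (1 - enrichment) * .ISOTOPES$N$abundance[2]
    enriched_n <- .atom_dist("N", abundance = c(1 - p15, p15))
    env <- .env_convolve(env, .env_power(enriched_n, n_labeled_n))
    # drop leading zero-probability bins so the envelope starts at its
    # lightest populated isotopologue
    first <- which(env$p > 0)[1]
    if (first > 1) {
      env$p <- env$p[first:length(env$p)]
      env$m <- env$m[first:length(env$m)]
    }
  }
  .as_envelope(env, n_peaks,
               meta = list(labeling = "enriched", n_labeled_n = n_labeled_n,
                           enrichment = enrichment))
}

#' @export
print.isotopic_envelope <- function(x, ...) {
  cat("Aggregated isotopic envelope:", nrow(x), "peaks,",
      sprintf("truncated mass %.2e", attr(x, "truncated_mass")), "\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Serialize an envelope to CSV (debugging aid)
#' @param env An `isotopic_envelope`.
#' @param path File path.
#' @export
write_envelope <- function(env, path) {
  utils::write.csv(as.data.frame(env), path, row.names = FALSE)
  invisible(path)
}

# shift an envelope's mass scale to ion m/z under an ion_spec
.envelope_as_ion <- function(env, ion) {
  cation <- .ADDUCTS[[ion$adduct]] - .ELECTRON_MASS
  env$mz <- (env$mz + ion$charge * cation) / ion$charge
  env
}
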