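# Atomic masses and isotope abundances (IUPAC/CIAAW 2021 values, monoisotopic
# masses in Da). Only the elements occurring in native and permethylated
# glycans plus the sodium adduct are carried.

.ISOTOPES <- list(
  H = list(shift = c(0L, 1L),
           mass = c(1.00782503207, 2.01410177785),
           abundance = c(0.999885, 0.000115)),
  C = list(shift = c(0L, 1L),
           mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  N = list(shift = c(0L, 1L),
           mass = c(14.00307400443, 15.00010889888),
           abundance = c(0.99636, 0.00364)),
  O = list(shift = c(0L, 1L, 2L),
           mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205)),
  Na = list(shift = 0L,
            mass = 22.98976928,
            abundance = 1.0)
)

.ELECTRON_MASS <- 0.000548579909

# 15N - 14N monoisotopic mass difference; the per-labeled-nitrogen shift of
# a heavy-channel glycan.
.N15_SHIFT <- .ISOTOPES$N$mass[2] - .ISOTOPES$N$mass[1]

#' Isotope table used by the package
#'
#' Returns the embedded table of isotopic masses and natural abundances
#' (elements H, C, N, O, Na) that every mass and envelope computation in
#' the package is based on.
#'
#' @return A data.frame with columns `element`, `mass_shift` (neutron count
#'   above the lightest isotope), `mass` (Da) and `abundance`.
#' @export
isotope_table <- function() {
  do.call(rbind, lapply(names(.ISOTOPES), function(el) {
    iso <- .ISOTOPES[[el]]
    data.frame(element = el, mass_shift = iso$shift, mass = iso$mass,
               abundance = iso$abundance, stringsAsFactors = FALSE)
  }))
}

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector mapping element symbols to
#' non-negative counts. Formulas add element-wise.
#'
#' @param ... Element counts, e.g. `elemental_formula(C = 6, H = 10, O = 5)`.
#' @return An object of class `elemental_formula`.
#' @export
elemental_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0)
    return(structure(integer(0), names = character(0),
                     class = "elemental_formula"))
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("all elements must be named")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  unknown <- setdiff(names(counts), names(.ISOTOPES))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  counts <- tapply(counts, names(counts), sum)  # merge duplicates
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) cat("<empty formula>\n")
  else cat(paste0(names(nz), nz, collapse = " "), "\n")
  invisible(x)
}

#' Add two elemental formulas element-wise
#'
#' @param f1,f2 `elemental_formula` objects.
#' @return Their element-wise sum.
#' @export
formula_add <- function(f1, f2) {
  all_el <- union(names(f1), names(f2))
  out <- vapply(all_el, function(el) {
    sum(c(f1[el], f2[el]), na.rm = TRUE)
  }, numeric(1))
  out <- as.integer(out)
  names(out) <- all_el
  structure(out, class = "elemental_formula")
}

#' Scale an elemental formula by an integer multiplier
#' @param f An `elemental_formula`.
#' @param k Non-negative integer.
#' @return The scaled formula.
#' @export
formula_multiply <- function(f, k) {
  stopifnot(k >= 0, k == round(k))
  out <- as.integer(unclass(f) * k)
  names(out) <- names(f)
  structure(out, class = "elemental_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' @param f An `elemental_formula`.
#' @return Monoisotopic (lightest-isotope) mass in Da.
#' @export
formula_mass <- function(f) {
  if (!length(f)) return(0)
  sum(vapply(names(f), function(el) .ISOTOPES[[el]]$mass[1] * f[[el]],
             numeric(1)))
}

# total nitrogen atoms in a formula
formula_nitrogens <- function(f) {
  n <- f["N"]
  if (is.na(n)) 0L else as.integer(n)
}
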