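# Monosaccharide residue chemistry: compositions, formulas, monoisotopic
# masses (native and permethylated), adducts, labeled-nitrogen counting and
# the theoretical m/z library.
#
# Residue formulas are those of the glycosidically linked residue, i.e. the
# free monosaccharide minus water. Aminosugar residues (HexNAc, NeuAc) carry
# one amide nitrogen derived from Gln via the hexosamine pathway; that
# nitrogen is the site of metabolic 15N labeling.

.RESIDUES <- list(
  HexNAc = list(formula = c(C = 8L, H = 13L, N = 1L, O = 5L),
                nitrogen_count = 1L, perm_ch2 = 3L),
  Hex    = list(formula = c(C = 6L, H = 10L, O = 5L),
                nitrogen_count = 0L, perm_ch2 = 3L),
  Fuc    = list(formula = c(C = 6L, H = 10L, O = 4L),
                nitrogen_count = 0L, perm_ch2 = 2L),
  NeuAc  = list(formula = c(C = 11L, H = 17L, N = 1L, O = 8L),
                nitrogen_count = 1L, perm_ch2 = 5L)
)

.CH2_MASS <- 14.01565006  # one methylation increment (CH2)
.WATER_FORMULA <- c(H = 2L, O = 1L)
# Permethylated free-glycan end groups: fixed increment over the sum of
# permethylated residue masses, calibrated so that permethylated
# HexNAc4Hex5 [M+Na]+ lands at ~2070.0.
.PERM_END_GROUP <- 46.0055

.ADDUCTS <- list(
  Na = .ISOTOPES$Na$mass[1],
  H  = .ISOTOPES$H$mass[1]
)

#' Monosaccharide residue table
#'
#' The four residue classes handled by the package, with the elemental
#' formula of the glycosidically linked residue (free sugar minus water),
#' its monoisotopic mass, its permethylated residue mass, and the number of
#' Gln-derived amide nitrogens (the 15N labeling sites).
#'
#' @return A data.frame with one row per residue class.
#' @export
residue_table <- function() {
  do.call(rbind, lapply(names(.RESIDUES), function(nm) {
    r <- .RESIDUES[[nm]]
    f <- do.call(elemental_formula, as.list(r$formula))
    m <- formula_mass(f)
    data.frame(name = nm,
               formula = paste0(names(r$formula), r$formula, collapse = ""),
               monoisotopic_residue_mass = m,
               nitrogen_count = r$nitrogen_count,
               permethylated_residue_mass = m + r$perm_ch2 * .CH2_MASS,
               stringsAsFactors = FALSE)
  }))
}

#' Construct a glycan composition
#'
#' A glycan composition is a multiset of monosaccharide residue classes:
#' counts of HexNAc, Hex, Fuc (deoxyhexose) and NeuAc. It is the unit of
#' identification and quantification; no topology or linkage is implied.
#'
#' @param hexnac,hex,fuc,neuac Non-negative integer residue counts.
#' @return An object of class `glycan_composition`.
#' @examples
#' glycan(hexnac = 2, hex = 6)   # Man6 high-mannose core composition
#' @export
glycan <- function(hexnac = 0, hex = 0, fuc = 0, neuac = 0) {
  counts <- c(HexNAc = hexnac, Hex = hex, Fuc = fuc, NeuAc = neuac)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("residue counts must be non-negative integers")
  structure(as.integer(counts), names = names(counts),
            class = "glycan_composition")
}

is_valid_glycan <- function(comp) {
  inherits(comp, "glycan_composition") && sum(comp) > 0
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(composition_string(x), "\n")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) composition_string(x)

#' Composition string of a glycan
#'
#' @param comp A `glycan_composition`.
#' @param compact If `TRUE`, the compact alias ("H6N2" style: H = Hex,
#'   N = HexNAc, F = Fuc, S = NeuAc, zero counts omitted) instead of the
#'   full "HexNAc2Hex6" form (zero counts also omitted).
#' @return A character scalar.
#' @export
composition_string <- function(comp, compact = FALSE) {
  if (compact) {
    key <- c(Hex = "H", HexNAc = "N", Fuc = "F", NeuAc = "S")
    parts <- vapply(names(key), function(nm) {
      if (comp[[nm]] > 0) paste0(key[[nm]], comp[[nm]]) else ""
    }, character(1))
  } else {
    parts <- vapply(names(comp), function(nm) {
      if (comp[[nm]] > 0) paste0(nm, comp[[nm]]) else ""
    }, character(1))
  }
  paste0(parts[nzchar(parts)], collapse = "")
}

#' Parse a glycan composition string
#'
#' Accepts the full form ("HexNAc2Hex6Fuc1", any order, zero counts and a
#' trailing count of 1 may be omitted, as in "HexNAc5Hex5Fuc").
#'
#' @param x Character scalar.
#' @return A `glycan_composition`.
#' @export
parse_glycan <- function(x) {
  s <- gsub("[[:space:]_]", "", x)
  counts <- c(HexNAc = 0L, Hex = 0L, Fuc = 0L, NeuAc = 0L)
  pat <- "(HexNAc|Hex|Fuc|dHex|NeuAc)([0-9]*)"
  m <- gregexpr(pat, s)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(s))
    stop("cannot parse glycan composition: ", x)
  for (tok in regmatches(s, m)[[1]]) {
    nm <- sub("^(HexNAc|Hex|Fuc|dHex|NeuAc).*", "\\1", tok)
    if (nm == "dHex") nm <- "Fuc"
    k <- sub("^(HexNAc|Hex|Fuc|dHex|NeuAc)", "", tok)
    counts[nm] <- counts[nm] + if (nzchar(k)) as.integer(k) else 1L
  }
  glycan(counts[["HexNAc"]], counts[["Hex"]], counts[["Fuc"]], counts[["NeuAc"]])
}

#' Number of Gln-derived (labelable) amide nitrogens in a composition
#'
#' In amide-15N-Gln metabolic labeling, each aminosugar residue (HexNAc,
#' NeuAc) carries exactly one heavy-labelable nitrogen; Hex and Fuc carry
#' none. The heavy-light mass shift of a glycan is this count times the
#' 15N-14N mass difference (0.99703 Da).
#'
#' @param comp A `glycan_composition`.
#' @return Integer count.
#' @export
labeled_nitrogens <- function(comp) {
  if (!is_valid_glycan(comp)) stop("invalid or empty glycan composition")
  as.integer(comp[["HexNAc"]] + comp[["NeuAc"]])
}

#' Ion specification
#'
#' Describes how a glycan composition is observed: adduct, charge,
#' derivatization, labeling state and 15N enrichment at the labeled
#' positions. The package default is the singly charged sodiated ion of the
#' native (underivatized) glycan, the dominant species in positive-mode
#' MALDI of neutral N-glycans.
#'
#' @param adduct Adduct cation, `"Na"` (default) or `"H"`.
#' @param charge Positive integer charge (default 1).
#' @param derivatization `"native"` or `"permethylated"`.
#' @param labeling `"light"` (amide-14N) or `"heavy"` (amide-15N).
#' @param enrichment Fraction of labeled nitrogens that are 15N in the
#'   heavy channel (default 1.0; 0.98 matches 98%-purity amide-15N-Gln).
#' @return An object of class `ion_spec`.
#' @export
ion_spec <- function(adduct = "Na", charge = 1L,
                     derivatization = c("native", "permethylated"),
                     labeling = c("light", "heavy"), enrichment = 1.0) {
  derivatization <- match.arg(derivatization)
  labeling <- match.arg(labeling)
  if (!adduct %in% names(.ADDUCTS))
    stop("unsupported adduct: ", adduct)
  if (charge < 1 || charge != round(charge)) stop("charge must be >= 1")
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  structure(list(adduct = adduct, charge = as.integer(charge),
                 derivatization = derivatization, labeling = labeling,
                 enrichment = enrichment),
            class = "ion_spec")
}

#' Elemental formula of a glycan composition
#'
#' Element-wise sum of the residue formulas plus one water (the free,
#' reduced-end glycan). The permethylated variant adds one CH2 per
#' methylation site consistently with the permethylated residue masses;
#' the fixed end-group increment of the permethylated mass scale is not an
#' integer number of CH2 and is carried on the mass route only.
#'
#' @param comp A `glycan_composition`.
#' @param derivatization `"native"` (default) or `"permethylated"`.
#' @return An `elemental_formula`. An all-zero composition returns the
#'   formula of water.
#' @export
composition_formula <- function(comp, derivatization = c("native", "permethylated")) {
  derivatization <- match.arg(derivatization)
  f <- do.call(elemental_formula, as.list(.WATER_FORMULA))
  ch2 <- elemental_formula(C = 1, H = 2)
  for (nm in names(comp)) {
    k <- comp[[nm]]
    if (k == 0) next
    f <- formula_add(f, formula_multiply(
      do.call(elemental_formula, as.list(.RESIDUES[[nm]]$formula)), k))
    if (derivatization == "permethylated")
      f <- formula_add(f, formula_multiply(ch2, k * .RESIDUES[[nm]]$perm_ch2))
  }
  f
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' @param comp A `glycan_composition`.
#' @param derivatization `"native"` or `"permethylated"`. The permethylated
#'   mass is the sum of permethylated residue masses plus a fixed end-group
#'   increment of 46.0055 Da.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(comp, derivatization = c("native", "permethylated")) {
  derivatization <- match.arg(derivatization)
  if (!is_valid_glycan(comp)) stop("invalid or empty glycan composition")
  if (derivatization == "native") {
    formula_mass(composition_formula(comp, "native"))
  } else {
    rt <- residue_table()
    sum(rt$permethylated_residue_mass[match(names(comp), rt$name)] * comp) +
      .PERM_END_GROUP
  }
}

#' Theoretical m/z of a glycan composition under an ion specification
#'
#' Monoisotopic m/z of the specified adduct:
#' (neutral mass + n x adduct cation mass) / charge, where the cation mass
#' accounts for the lost electrons. The heavy labeling state (at enrichment
#' 1.0) adds `labeled_nitrogens(comp)` times the 15N-14N mass difference
#' (0.99703 Da) to the monoisotopic position. At enrichment < 1 the
#' monoisotopic (all-14N) position is unchanged but its abundance is
#' negligible; this function always reports the fully labeled position for
#' the heavy state, which is the envelope's dominant leading peak.
#'
#' @param comp A `glycan_composition`.
#' @param ion An `ion_spec`; default singly sodiated native light ion.
#' @return m/z in Da.
#' @examples
#' composition_mass(glycan(hexnac = 2, hex = 6))        # 1419.48
#' composition_mass(glycan(hexnac = 5, hex = 5, fuc = 1))  # 2012.72
#' @export
composition_mass <- function(comp, ion = ion_spec()) {
  stopifnot(inherits(ion, "ion_spec"))
  m <- neutral_mass(comp, ion$derivatization)
  if (ion$labeling == "heavy")
    m <- m + labeled_nitrogens(comp) * .N15_SHIFT
  cation <- .ADDUCTS[[ion$adduct]] - .ELECTRON_MASS
  (m + ion$charge * cation) / ion$charge
}

#' Enumerate a theoretical composition library
#'
#' Builds all compositions over the given residue count ranges, with the
#' theoretical light and heavy m/z of each under the given ion spec. The
#' default ranges cover the compositions observed in dual-labeled ovarian
#' cancer secretome profiling (HexNAc 2-8, Hex 3-10, Fuc 0-2, NeuAc 0-4).
#'
#' @param hexnac,hex,fuc,neuac Integer vectors of allowed counts.
#' @param ion An `ion_spec` for the reported m/z (labeling field ignored;
#'   both states are reported).
#' @return A data.frame sorted by ascending light m/z with columns
#'   `composition`, `alias`, `hexnac`, `hex`, `fuc`, `neuac`,
#'   `neutral_mass`, `mz_light`, `mz_heavy`, `n_labeled`.
#' @export
build_library <- function(hexnac = 2:8, hex = 3:10, fuc = 0:2, neuac = 0:4,
                          ion = ion_spec()) {
  grid <- expand.grid(hexnac = hexnac, hex = hex, fuc = fuc, neuac = neuac,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- unique(grid)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  if (nrow(grid) == 0) {
    return(data.frame(composition = character(0), alias = character(0),
                      hexnac = integer(0), hex = integer(0), fuc = integer(0),
                      neuac = integer(0), neutral_mass = numeric(0),
                      mz_light = numeric(0), mz_heavy = numeric(0),
                      n_labeled = integer(0), stringsAsFactors = FALSE))
  }
  ion_l <- ion; ion_l$labeling <- "light"
  ion_h <- ion; ion_h$labeling <- "heavy"; ion_h$enrichment <- 1.0
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    comp <- glycan(grid$hexnac[i], grid$hex[i], grid$fuc[i], grid$neuac[i])
    data.frame(composition = composition_string(comp),
               alias = composition_string(comp, compact = TRUE),
               hexnac = comp[["HexNAc"]], hex = comp[["Hex"]],
               fuc = comp[["Fuc"]], neuac = comp[["NeuAc"]],
               neutral_mass = neutral_mass(comp, ion$derivatization),
               mz_light = composition_mass(comp, ion_l),
               mz_heavy = composition_mass(comp, ion_h),
               n_labeled = labeled_nitrogens(comp),
               stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, rows)
  lib <- lib[order(lib$mz_light, lib$composition), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Write / read a composition library as CSV
#'
#' @param lib A library data.frame from [build_library()].
#' @param path File path.
#' @return `read_glycan_library` returns the library data.frame.
#' @export
write_glycan_library <- function(lib, path) {
  utils::write.csv(lib, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_glycan_library
#' @export
read_glycan_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("composition", "hexnac", "hex", "fuc", "neuac", "mz_light")
  missing <- setdiff(needed, names(lib))
  if (length(missing))
    stop("library file lacks column(s): ", paste(missing, collapse = ", "))
  lib
}

# glycan_composition from a library row
library_row_glycan <- function(lib, i) {
  glycan(lib$hexnac[i], lib$hex[i], lib$fuc[i], lib$neuac[i])
}
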