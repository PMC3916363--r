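# Peak-to-composition assignment, glycan class annotation (flagging
# bisecting GlcNAc) and MS/MS glycosidic fragment mass enumeration.

.GLYCAN_CLASSES <- c("High mannose", "Hybrid", "Complex biantennary",
                     "Triantennary", "Tetra-antennary", "Bisecting")

#' Curated composition-to-class map
#'
#' Loads the curated map transcribing the manually interpreted structure
#' classes of the SKOV3-ip/SKOV3 secretome panel. Composition alone cannot
#' distinguish a bisecting GlcNAc from an antennary isomer (e.g.
#' HexNAc5Hex5 bisecting vs triantennary agalacto); these entries encode
#' the MS/MS- and database-supported interpretation, and they override the
#' composition heuristic in [classify_glycan()].
#'
#' @param path Path to a curated-class CSV (columns `composition`,
#'   `glycan_class`, `bisecting`); default the map shipped with the
#'   package.
#' @return A data.frame.
#' @export
curated_classes <- function(path = system.file("extdata",
                                               "skov3_curated_classes.csv",
                                               package = "glycoquant")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("composition", "glycan_class", "bisecting") %in% names(map)))
  map$bisecting <- as.logical(map$bisecting)
  map
}

#' Match observed peaks against a composition library
#'
#' Each peak receives the nearest library entry within `tolerance` (Da) of
#' its m/z, or no assignment. Ties are broken by smaller absolute mass
#' error, then lexicographically by composition string. Other library
#' entries within tolerance are reported as the ambiguity list, sorted by
#' absolute error. Unassigned peaks are reported, not dropped.
#'
#' @param peaks A `peak_list` (or data.frame with an `mz` column).
#' @param library A library data.frame from [build_library()].
#' @param tolerance Match tolerance in Da (default 0.3).
#' @return A data.frame with one row per input peak: `observed_mz`,
#'   `intensity`, `assigned` (logical), `composition`, `theoretical_mz`,
#'   `mass_error`, `n_ambiguous`, `ambiguity` (semicolon-separated
#'   alternatives).
#' @export
match_peaks <- function(peaks, library, tolerance = 0.3) {
  if (nrow(library) == 0) stop("library must be non-empty")
  if (tolerance <= 0) stop("tolerance must be > 0")
  mz <- peaks$mz
  out <- lapply(seq_along(mz), function(i) {
    err <- library$mz_light - mz[i]
    hit <- which(abs(err) <= tolerance)
    if (!length(hit)) {
      return(data.frame(observed_mz = mz[i],
                        intensity = peaks$intensity[i],
                        assigned = FALSE, composition = NA_character_,
                        theoretical_mz = NA_real_, mass_error = NA_real_,
                        n_ambiguous = 0L, ambiguity = "",
                        stringsAsFactors = FALSE))
    }
    hit <- hit[order(abs(err[hit]), library$composition[hit])]
    best <- hit[1]
    data.frame(observed_mz = mz[i], intensity = peaks$intensity[i],
               assigned = TRUE, composition = library$composition[best],
               theoretical_mz = library$mz_light[best],
               mass_error = mz[i] - library$mz_light[best],
               n_ambiguous = length(hit) - 1L,
               ambiguity = paste(library$composition[hit[-1]],
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter a peak list to candidate monoisotopic peaks
#'
#' A centroided glycan cluster contributes ~10 isotopologue peaks at ~1 Da
#' spacing; only the leading (monoisotopic) peak should be matched against
#' a library of monoisotopic m/z values. A peak is kept unless another peak
#' sits one isotopologue spacing below it with at least `min_frac` of its
#' intensity — the signature of being an isotopic satellite rather than a
#' cluster leader.
#'
#' @param peaks A `peak_list`.
#' @param spacing Isotopologue spacing in Da (default 1.0034).
#' @param tol Spacing tolerance in Da (default 0.3).
#' @param min_frac Intensity fraction of the peak below that marks a
#'   satellite (default 0.3).
#' @return The filtered `peak_list`.
#' @export
monoisotopic_peaks <- function(peaks, spacing = 1.0034, tol = 0.3,
                               min_frac = 0.3) {
  if (nrow(peaks) < 2) return(peaks)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    d <- peaks$mz[i] - peaks$mz
    below <- which(d >= spacing - tol & d <= spacing + tol)
    !any(peaks$intensity[below] >= min_frac * peaks$intensity[i])
  }, logical(1))
  peak_list(peaks$mz[keep], peaks$intensity[keep], peaks$area[keep],
            normalized = isTRUE(attr(peaks, "normalized")))
}

# composition heuristic when no curated entry exists: antenna count from
# HexNAc beyond the chitobiose core
.heuristic_class <- function(comp) {
  n <- comp[["HexNAc"]]
  if (n == 2 && comp[["Fuc"]] == 0) "High mannose"
  else if (n == 2) "Complex biantennary"  # paucimannose-fucosylated fallback
  else if (n == 3) "Hybrid"
  else if (n == 4) "Complex biantennary"
  else if (n == 5) "Triantennary"
  else "Tetra-antennary"
}

#' Classify a glycan composition into a structure class
#'
#' Consults the curated map first; compositions absent from it fall back to
#' a composition heuristic (HexNAc2 without Fuc: high mannose; HexNAc3:
#' hybrid; HexNAc4: complex biantennary; HexNAc >= 5: antennary guess,
#' flagged ambiguous because bisecting vs antennary isomers cannot be told
#' apart from composition alone). Sialylated compositions inherit the class
#' of their desialylated parent. A bisecting flag is set iff the class is
#' "Bisecting".
#'
#' @param comp A `glycan_composition`.
#' @param curated Curated map data.frame (default [curated_classes()]).
#' @return A list of class `structure_annotation`: `composition`,
#'   `glycan_class`, `bisecting`, `provenance` ("curated" or "heuristic"),
#'   `ambiguous`.
#' @export
classify_glycan <- function(comp, curated = curated_classes()) {
  if (!is_valid_glycan(comp)) stop("invalid or empty glycan composition")
  parent <- comp
  if (comp[["NeuAc"]] > 0)  # sialylated variants inherit the parent class
    parent <- glycan(comp[["HexNAc"]], comp[["Hex"]], comp[["Fuc"]], 0)
  key <- composition_string(parent)
  idx <- match(key, curated$composition)
  if (!is.na(idx)) {
    ann <- list(composition = composition_string(comp),
                glycan_class = curated$glycan_class[idx],
                bisecting = isTRUE(curated$bisecting[idx]),
                provenance = "curated", ambiguous = FALSE)
  } else {
    cls <- .heuristic_class(parent)
    ann <- list(composition = composition_string(comp),
                glycan_class = cls,
                bisecting = identical(cls, "Bisecting"),
                provenance = "heuristic",
                ambiguous = parent[["HexNAc"]] >= 5)
    if (ann$ambiguous)
      warning("class of ", key, " is ambiguous without MS/MS evidence; ",
              "heuristic '", cls, "' assigned", call. = FALSE)
  }
  structure(ann, class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("%s -> %s%s (%s%s)\n", x$composition, x$glycan_class,
              if (x$bisecting) " [bisecting GlcNAc]" else "",
              x$provenance, if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

# bookkeeping constant of complementary B/Y fragment pairs: both fragments
# are sodiated, so mass(B) + mass(Y) = precursor m/z + Na+ mass
.FRAGMENT_COMPLEMENT_CONSTANT <- function() .ADDUCTS$Na - .ELECTRON_MASS
.WATER_MASS <- 18.01056468

#' Glycosidic B/Y fragment masses of a sodiated precursor
#'
#' Enumerates composition-level glycosidic-bond cleavages of a sodiated
#' precursor: Y ions retain the reducing end (precursor minus a sub-multiset
#' of up to `max_losses` residues), B ions are the complementary
#' non-reducing fragments. Each fragment optionally carries a water-loss
#' variant (-18.011 Da). Fragments are deduplicated by m/z (topology is not
#' modeled, so distinct losses of the same residue multiset coincide).
#'
#' @param comp Precursor `glycan_composition`.
#' @param max_losses Maximum number of residues lost (default 2).
#' @param water_loss Include -H2O variants (default TRUE).
#' @return A data.frame with columns `type` ("B"/"Y"), `lost`, `retained`,
#'   `mz`, `water_loss`, sorted by ascending m/z.
#' @export
fragment_masses <- function(comp, max_losses = 2L, water_loss = TRUE) {
  if (!is_valid_glycan(comp)) stop("invalid or empty glycan composition")
  rt <- residue_table()
  res_mass <- stats::setNames(rt$monoisotopic_residue_mass, rt$name)
  prec_mz <- composition_mass(comp)
  losses <- expand.grid(HexNAc = 0:comp[["HexNAc"]], Hex = 0:comp[["Hex"]],
                        Fuc = 0:comp[["Fuc"]], NeuAc = 0:comp[["NeuAc"]])
  tot <- rowSums(losses)
  losses <- losses[tot >= 1 & tot <= max_losses & tot < sum(comp), ,
                   drop = FALSE]
  if (nrow(losses) == 0)
    return(data.frame(type = character(0), lost = character(0),
                      retained = character(0), mz = numeric(0),
                      water_loss = logical(0)))
  rows <- lapply(seq_len(nrow(losses)), function(i) {
    lost <- glycan(losses$HexNAc[i], losses$Hex[i], losses$Fuc[i],
                   losses$NeuAc[i])
    lost_mass <- sum(res_mass[names(lost)] * lost)
    y_mz <- prec_mz - lost_mass                       # sodiated Y ion
    b_mz <- lost_mass + .FRAGMENT_COMPLEMENT_CONSTANT()  # sodiated B ion
    retained <- glycan(comp[["HexNAc"]] - lost[["HexNAc"]],
                       comp[["Hex"]] - lost[["Hex"]],
                       comp[["Fuc"]] - lost[["Fuc"]],
                       comp[["NeuAc"]] - lost[["NeuAc"]])
    base <- data.frame(
      type = c("Y", "B"),
      lost = composition_string(lost),
      retained = c(composition_string(retained), composition_string(lost)),
      mz = c(y_mz, b_mz),
      water_loss = FALSE, stringsAsFactors = FALSE)
    if (water_loss) {
      wl <- base; wl$mz <- wl$mz - .WATER_MASS; wl$water_loss <- TRUE
      base <- rbind(base, wl)
    }
    base
  })
  frags <- do.call(rbind, rows)
  frags <- frags[frags$mz < prec_mz, , drop = FALSE]
  frags <- frags[!duplicated(round(frags$mz, 6)), , drop = FALSE]
  frags <- frags[order(frags$mz), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}
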