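# Residue chemistry, composition masses and the theoretical m/z library.

test_that("residue masses agree with an independent atomic-mass table", {
  rt <- residue_table()
  expected <- list(
    HexNAc = c(C = 8, H = 13, N = 1, O = 5),
    Hex    = c(C = 6, H = 10, O = 5),
    Fuc    = c(C = 6, H = 10, O = 4),
    NeuAc  = c(C = 11, H = 17, N = 1, O = 8))
  for (nm in names(expected)) {
    row <- rt[rt$name == nm, ]
    expect_equal(row$monoisotopic_residue_mass,
                 oracle_monoisotopic_mass(expected[[nm]]),
                 tolerance = 1e-9, info = nm)
    expect_equal(row$nitrogen_count,
                 as.integer(ifelse(is.na(expected[[nm]]["N"]), 0,
                                   expected[[nm]]["N"])), info = nm)
  }
})

test_that("labeled nitrogen count is one per aminosugar residue", {
  expect_identical(labeled_nitrogens(glycan(2, 6)), 2L)
  expect_identical(labeled_nitrogens(glycan(7, 7, 1)), 7L)
  expect_identical(labeled_nitrogens(glycan(0, 9)), 0L)
  expect_identical(labeled_nitrogens(glycan(3, 5, 0, 2)), 5L)
  expect_error(labeled_nitrogens(glycan(0, 0)), "empty")
})

test_that("theoretical m/z reproduces the 17-glycan reference panel at 1 d.p.", {
  panel <- skov3_panel()
  for (i in seq_len(nrow(panel))) {
    mz <- composition_mass(parse_glycan(panel$composition[i]))
    expect_lte(abs(round(mz, 1) - panel$theoretical_mz[i]), 0.05)
  }
})

test_that("heavy - light m/z difference is labeled_nitrogens x 0.99703 exactly", {
  shift_15n <- 15.00010889888 - 14.00307400443
  for (comp in list(glycan(2, 6), glycan(5, 5, 1), glycan(7, 7, 1),
                    glycan(3, 5, 0, 2))) {
    d <- composition_mass(comp, ion_spec(labeling = "heavy")) -
      composition_mass(comp, ion_spec(labeling = "light"))
    expect_equal(d, labeled_nitrogens(comp) * shift_15n, tolerance = 1e-12)
  }
})

test_that("composition_formula and composition_mass agree through the atom table", {
  panel <- skov3_panel()
  for (s in panel$composition) {
    comp <- parse_glycan(s)
    expect_equal(formula_mass(composition_formula(comp)),
                 composition_mass(comp, ion_spec(adduct = "Na")) -
                   (22.98976928 - 0.000548579909),
                 tolerance = 1e-9, info = s)
  }
  # additive identity: empty composition's formula is water
  f0 <- composition_formula(glycan(0, 0))
  expect_equal(formula_mass(f0), oracle_monoisotopic_mass(c(H = 2, O = 1)),
               tolerance = 1e-9)
  # single hexose: glucose monoisotopic mass
  expect_equal(formula_mass(composition_formula(glycan(0, 1))), 180.06339,
               tolerance = 1e-4)
})

test_that("neutral native mass is additive over residues (minus the shared water)", {
  water <- oracle_monoisotopic_mass(c(H = 2, O = 1))
  pairs <- list(list(glycan(2, 3), glycan(1, 2, 1)),
                list(glycan(1, 0, 0, 1), glycan(0, 5)),
                list(glycan(4, 4), glycan(3, 3, 2, 1)))
  for (p in pairs) {
    c1 <- p[[1]]; c2 <- p[[2]]
    merged <- glycan(c1[["HexNAc"]] + c2[["HexNAc"]], c1[["Hex"]] + c2[["Hex"]],
                     c1[["Fuc"]] + c2[["Fuc"]], c1[["NeuAc"]] + c2[["NeuAc"]])
    expect_equal(neutral_mass(merged),
                 neutral_mass(c1) + neutral_mass(c2) - water,
                 tolerance = 1e-9)
  }
})

test_that("permethylated mass scale matches its calibration point", {
  # permethylated HexNAc4Hex5 sodiated lands at ~2070.0
  mz <- composition_mass(glycan(4, 5),
                         ion_spec(derivatization = "permethylated"))
  expect_equal(round(mz, 1), 2070.0, tolerance = 0.051)
  # the sialylated-series parent: residue-sum arithmetic gives ~2489.2
  mz2 <- composition_mass(glycan(5, 5, 1),
                          ion_spec(derivatization = "permethylated"))
  expect_equal(mz2, 2489.21, tolerance = 0.05)
})

test_that("composition parsing and formatting round-trip", {
  for (s in c("HexNAc2Hex6", "HexNAc5Hex5Fuc1", "HexNAc3Hex5Fuc2NeuAc1")) {
    expect_identical(composition_string(parse_glycan(s)), s)
  }
  # trailing count of 1 may be omitted, underscores ignored
  expect_identical(composition_string(parse_glycan("HexNAc5Hex5 Fuc")),
                   "HexNAc5Hex5Fuc1")
  expect_identical(composition_string(parse_glycan("HexNAc_2_Hex_6_")),
                   "HexNAc2Hex6")
  expect_identical(composition_string(glycan(2, 6), compact = TRUE), "H6N2")
  expect_error(parse_glycan("NotAGlycan"), "parse")
})

test_that("library enumeration covers the panel, is sorted and deduplicated", {
  lib <- build_library(2:8, 3:10, 0:2, 0)
  panel <- skov3_panel()
  idx <- match(panel$composition, lib$composition)
  expect_false(anyNA(idx))
  expect_true(all(abs(round(lib$mz_light[idx], 1) - panel$theoretical_mz)
                  <= 0.05))
  expect_true(!is.unsorted(lib$mz_light))
  expect_identical(anyDuplicated(lib$composition), 0L)
  # empty ranges give an empty library, not an error
  empty <- build_library(0, 0, 0, 0)
  expect_identical(nrow(empty), 0L)
})

test_that("library CSV round-trips", {
  lib <- build_library(2:3, 3:4, 0:1, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_glycan_library(lib, path)
  back <- read_glycan_library(path)
  expect_equal(back$mz_light, lib$mz_light, tolerance = 1e-9)
  expect_identical(back$composition, lib$composition)
  expect_identical(back$alias, lib$alias)
})

test_that("invalid inputs are rejected", {
  expect_error(glycan(-1, 2), "non-negative")
  expect_error(composition_mass(glycan(0, 0)), "empty")
  expect_error(ion_spec(adduct = "K"), "adduct")
  expect_error(ion_spec(enrichment = 1.5), "enrichment")
  expect_error(ion_spec(charge = 0), "charge")
})
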