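# Peak assignment, class annotation and fragment enumeration.

panel <- skov3_panel()
lib <- build_library(2:8, 3:10, 0:2, 0)

test_that("panel peaks are assigned their printed compositions", {
  pk <- peak_list(panel$observed_mz, rep(1, 17))
  asn <- match_peaks(pk, lib, tolerance = 0.3)
  expect_identical(sum(asn$assigned), 17L)
  expect_identical(asn$composition, panel$composition)
  expect_true(all(abs(asn$mass_error) <= 0.3, na.rm = TRUE))
  # spot check the printed example
  one <- match_peaks(peak_list(1866.6, 1), lib, 0.3)
  expect_identical(one$composition, "HexNAc5Hex5")
  expect_equal(one$theoretical_mz, 1866.7, tolerance = 0.05)
})

test_that("peaks far from every library entry stay unassigned but reported", {
  pk <- peak_list(c(1419.5, 1424.5, 1430.0), c(5, 1, 2))
  asn <- match_peaks(pk, lib, 0.3)
  expect_identical(nrow(asn), 3L)  # unassigned rows are kept
  expect_identical(asn$assigned, c(TRUE, FALSE, FALSE))
  expect_identical(sum(asn$assigned) + sum(!asn$assigned), nrow(asn))
})

test_that("ambiguity lists are sorted by absolute error", {
  # with sialylated entries allowed, NeuAc1 sits only 1.02 Da above Fuc2
  lib_sial <- build_library(2:8, 3:10, 0:2, 0:2)
  wide <- match_peaks(peak_list(panel$observed_mz, rep(1, 17)), lib_sial,
                      tolerance = 2.0)
  expect_gt(sum(wide$n_ambiguous), 0)
  for (i in which(wide$n_ambiguous > 0)) {
    alts <- strsplit(wide$ambiguity[i], ";")[[1]]
    errs <- abs(lib_sial$mz_light[match(alts, lib_sial$composition)] -
                  wide$observed_mz[i])
    expect_true(!is.unsorted(errs))
    expect_lte(abs(wide$mass_error[i]), min(errs))
  }
})

test_that("curated map reproduces the panel's type column and bisecting rows", {
  for (i in seq_len(nrow(panel))) {
    ann <- classify_glycan(parse_glycan(panel$composition[i]))
    expect_identical(ann$glycan_class, panel$type[i], info = panel$composition[i])
    expect_identical(ann$provenance, "curated")
    expect_identical(ann$bisecting, panel$type[i] == "Bisecting")
  }
  bis <- panel$composition[panel$type == "Bisecting"]
  expect_setequal(bis, c("HexNAc5Hex5", "HexNAc5Hex5Fuc1",
                         "HexNAc6Hex6Fuc1", "HexNAc7Hex7Fuc1"))
})

test_that("heuristic fallback classifies by HexNAc count and flags ambiguity", {
  expect_identical(classify_glycan(glycan(2, 5))$glycan_class, "High mannose")
  expect_identical(classify_glycan(glycan(3, 4))$glycan_class, "Hybrid")
  h4 <- classify_glycan(glycan(4, 3, 1))
  expect_identical(h4$glycan_class, "Complex biantennary")
  expect_identical(h4$provenance, "heuristic")
  expect_false(h4$ambiguous)
  expect_warning(h5 <- classify_glycan(glycan(5, 4)), "ambiguous")
  expect_true(h5$ambiguous)
})

test_that("sialylated compositions inherit their desialylated parent's class", {
  ann <- classify_glycan(glycan(5, 5, 1, 1))  # HexNAc5Hex5Fuc1 + NeuAc
  expect_identical(ann$glycan_class, "Bisecting")
  expect_identical(ann$provenance, "curated")
})

test_that("B/Y fragments are complementary and grow with max_losses", {
  comp <- glycan(5, 5, 1)  # precursor 2012.7
  fr <- fragment_masses(comp, max_losses = 1, water_loss = FALSE)
  prec <- composition_mass(comp)
  # loss of one HexNAc gives the Y ion near 1809.6
  y1 <- fr[fr$type == "Y" & fr$lost == "HexNAc1", ]
  expect_equal(y1$mz, prec - 203.0794, tolerance = 1e-3)
  expect_equal(round(y1$mz, 1), 1809.6, tolerance = 0.051)
  # complement: mass(B) + mass(Y) = precursor + sodium cation
  na_cation <- 22.98976928 - 0.000548579909
  for (lost in unique(fr$lost)) {
    b <- fr$mz[fr$type == "B" & fr$lost == lost]
    y <- fr$mz[fr$type == "Y" & fr$lost == lost]
    if (length(b) && length(y))
      expect_equal(b + y, prec + na_cation, tolerance = 1e-9)
  }
  expect_true(all(fr$mz < prec))
  n1 <- nrow(fragment_masses(comp, 1))
  n2 <- nrow(fragment_masses(comp, 2))
  n3 <- nrow(fragment_masses(comp, 3))
  expect_true(n1 <= n2 && n2 <= n3)
  # losing everything is excluded
  small <- fragment_masses(glycan(1, 1), max_losses = 5)
  expect_false(any(small$lost == "HexNAc1Hex1"))
})

test_that("monoisotopic filtering keeps cluster leaders and drops satellites", {
  env <- natural_envelope(composition_formula(glycan(2, 6)))
  mz <- env$mz + 22.98922
  it <- 100 * env$abundance
  pk <- peak_list(mz, it, it)
  kept <- monoisotopic_peaks(pk)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$mz, mz[1], tolerance = 1e-6)
  # two separate clusters: both leaders survive
  pk2 <- peak_list(c(mz, mz + 50), c(it, it), c(it, it))
  expect_identical(nrow(monoisotopic_peaks(pk2)), 2L)
})
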