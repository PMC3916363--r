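# Curated reference panel: the 17 N-glycans detected in a published
# dual-labeled (amide-14N/15N-Gln) MALDI comparison of secretomes from the
# ovarian cancer cell line SKOV3 and its highly metastatic derivative
# SKOV3-ip (light channel = SKOV3-ip, heavy = SKOV3). The panel supplies
# observed and theoretical m/z, mean SKOV3-ip/SKOV3 ratios, replicate CV%
# (n = 9), change calls and the manually interpreted structure class of
# each composition. It drives the curated class map, the default synthetic
# scenario and the package's reference checks.

.SKOV3_PANEL <- data.frame(
  observed_mz = c(1419.5, 1460.4, 1581.5, 1622.4, 1647.5, 1663.6, 1743.5,
                  1809.6, 1866.6, 1905.5, 2012.7, 2028.6, 2158.6, 2174.7,
                  2377.8, 2539.9, 2742.9),
  theoretical_mz = c(1419.5, 1460.5, 1581.5, 1622.6, 1647.6, 1663.6, 1743.6,
                     1809.6, 1866.7, 1905.6, 2012.7, 2028.7, 2158.8, 2174.8,
                     2377.9, 2539.9, 2743.0),
  ratio = c(1.46, 2.05, 0.95, 1.63, 3.40, 3.23, 1.42, 2.21, 0.28, 2.19,
            0.12, 1.32, 0.64, 2.21, 0.32, 1.78, 0.73),
  cv_pct = c(4.26, 13.44, 3.49, 12.61, 11.48, 8.78, 4.29, 8.87, 2.40, 10.01,
             15.20, 18.06, 17.46, 15.99, 9.87, 15.90, 15.35),
  change = c("up", "up", "no", "up", "up", "up", "up", "up", "down", "up",
             "down", "up", "down", "up", "down", "up", "down"),
  composition = c("HexNAc2Hex6", "HexNAc3Hex5", "HexNAc2Hex7", "HexNAc3Hex6",
                  "HexNAc4Hex4Fuc1", "HexNAc4Hex5", "HexNAc2Hex8",
                  "HexNAc4Hex5Fuc1", "HexNAc5Hex5", "HexNAc2Hex9",
                  "HexNAc5Hex5Fuc1", "HexNAc5Hex6", "HexNAc5Hex5Fuc2",
                  "HexNAc5Hex6Fuc1", "HexNAc6Hex6Fuc1", "HexNAc6Hex7Fuc1",
                  "HexNAc7Hex7Fuc1"),
  type = c("High mannose", "Hybrid", "High mannose", "Hybrid",
           "Complex biantennary", "Complex biantennary", "High mannose",
           "Complex biantennary", "Bisecting", "High mannose", "Bisecting",
           "Triantennary", "Complex biantennary", "Triantennary",
           "Bisecting", "Tetra-antennary", "Bisecting"),
  stringsAsFactors = FALSE
)

#' Reference panel of 17 N-glycans from the SKOV3-ip/SKOV3 secretome comparison
#'
#' The curated panel of 17 N-glycan compositions detected in positive-mode
#' MALDI of a 1:1 mixture of amide-14N-Gln-labeled SKOV3-ip and
#' amide-15N-Gln-labeled SKOV3 secretomes: observed and theoretical
#' [M+Na]+ m/z, mean light/heavy (SKOV3-ip/SKOV3) ratio, replicate CV%
#' (n = 9), change call under the 0.83/1.20 thresholds, composition and
#' curated structure class. Four compositions carry a bisecting GlcNAc;
#' all four are down-regulated in the metastatic line.
#'
#' @return A data.frame with 17 rows and columns `observed_mz`,
#'   `theoretical_mz`, `ratio`, `cv_pct`, `change`, `composition`, `type`.
#' @export
skov3_panel <- function() .SKOV3_PANEL
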