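# Independent oracles used by the tests. These deliberately re-derive
# results by routes different from the package implementation: exhaustive
# multinomial enumeration for isotopic envelopes, an independently frozen
# atomic-mass table for residue masses, and a brute-force grid search for
# the two-template ratio fit.

# Frozen atomic-mass/abundance table (CIAAW), kept separate from the
# package's own embedded table.
ORACLE_ISO <- list(
  H = data.frame(shift = c(0, 1),
                 mass = c(1.00782503207, 2.01410177785),
                 p = c(0.999885, 0.000115)),
  C = data.frame(shift = c(0, 1),
                 mass = c(12.0, 13.00335483507),
                 p = c(0.9893, 0.0107)),
  N = data.frame(shift = c(0, 1),
                 mass = c(14.00307400443, 15.00010889888),
                 p = c(0.99636, 0.00364)),
  O = data.frame(shift = c(0, 1, 2),
                 mass = c(15.99491461957, 16.99913175650, 17.99915961286),
                 p = c(0.99757, 0.00038, 0.00205)),
  Na = data.frame(shift = 0, mass = 22.98976928, p = 1)
)

oracle_monoisotopic_mass <- function(counts) {
  sum(vapply(names(counts), function(el) {
    ORACLE_ISO[[el]]$mass[1] * counts[[el]]
  }, numeric(1)))
}

# all ways to distribute n atoms over k isotopes (compositions of n)
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    sub <- .compositions(n - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# Exhaustive aggregated envelope by enumerating every per-element isotope
# composition with multinomial probabilities. `enriched_n` labeled
# nitrogens (binomial at `enrichment`) are treated as a separate pseudo
# element. Returns data.frame(shift, p, mz) with centroid masses,
# normalized over all enumerated mass.
oracle_envelope <- function(counts, enriched_n = 0, enrichment = 1) {
  stopifnot(enriched_n <= ifelse(is.na(counts["N"]), 0, counts["N"]) ||
              enriched_n == 0)
  if (enriched_n > 0) counts["N"] <- counts["N"] - enriched_n
  per_el <- list()
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    iso <- ORACLE_ISO[[el]]
    cmb <- .compositions(n, nrow(iso))
    p <- apply(cmb, 1, function(v) stats::dmultinom(v, prob = iso$p))
    per_el[[el]] <- data.frame(
      shift = as.vector(cmb %*% iso$shift),
      mass = as.vector(cmb %*% iso$mass), p = p)
  }
  if (enriched_n > 0) {
    isoN <- ORACLE_ISO$N
    # labeled-pool purity model: impurity carries natural nitrogen
    p15 <- enrichment + (1 - enrichment) * isoN$p[2]
    k <- 0:enriched_n
    per_el[["N15lab"]] <- data.frame(
      shift = k,
      mass = k * isoN$mass[2] + (enriched_n - k) * isoN$mass[1],
      p = stats::dbinom(k, enriched_n, p15))
  }
  # cross-product over elements
  acc <- data.frame(shift = 0, mass = 0, p = 1)
  for (d in per_el) {
    acc <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
      data.frame(shift = acc$shift[i] + d$shift,
                 mass = acc$mass[i] + d$mass,
                 p = acc$p[i] * d$p)
    }))
    acc <- acc[acc$p > 1e-18, , drop = FALSE]
  }
  agg <- lapply(split(acc, acc$shift), function(g) {
    data.frame(shift = g$shift[1], p = sum(g$p),
               mz = sum(g$mass * g$p) / sum(g$p))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$shift), , drop = FALSE]
  out$shift <- out$shift - out$shift[1]
  out$p <- out$p / sum(out$p)
  rownames(out) <- NULL
  out
}

# Brute-force two-parameter grid search of the same objective fit_pair
# minimizes: || y - a*L - b*H ||_2 over a, b >= 0 at the expected cluster
# positions. Clustering is re-derived here independently.
oracle_grid_ratio <- function(peaks, pair, tolerance = 0.3, n_grid = 60) {
  pos <- c(pair$light$mz, pair$heavy$mz)
  lab <- rep(c("L", "H"), c(nrow(pair$light), nrow(pair$heavy)))
  ab <- c(pair$light$abundance, pair$heavy$abundance)
  ord <- order(pos); pos <- pos[ord]; lab <- lab[ord]; ab <- ab[ord]
  cl <- cumsum(c(1, diff(pos) > 0.5))
  centers <- tapply(pos, cl, mean)
  L <- tapply(ab * (lab == "L"), cl, sum)
  H <- tapply(ab * (lab == "H"), cl, sum)
  vals <- if (any(peaks$area > 0)) peaks$area else peaks$intensity
  y <- vapply(centers, function(cm) sum(vals[abs(peaks$mz - cm) <= tolerance]),
              numeric(1))
  hi <- 2 * sum(y)
  a_grid <- seq(0, hi, length.out = n_grid)
  b_grid <- seq(0, hi, length.out = n_grid)
  best <- c(NA, NA); best_obj <- Inf
  for (rep in 1:4) {  # successive grid refinement
    for (a in a_grid) for (b in b_grid) {
      obj <- sum((y - a * L - b * H)^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(a, b) }
    }
    da <- diff(a_grid)[1]; db <- diff(b_grid)[1]
    a_grid <- seq(max(0, best[1] - 2 * da), best[1] + 2 * da,
                  length.out = n_grid)
    b_grid <- seq(max(0, best[2] - 2 * db), best[2] + 2 * db,
                  length.out = n_grid)
  }
  best[1] / best[2]
}

# noise-free single-pair peak list built directly from the theoretical
# envelopes (bypasses the generator)
make_pair_peaks <- function(comp, light_amt, heavy_amt, enrichment = 1,
                            n_peaks = 10L) {
  pair <- build_pair(comp, ion_spec(enrichment = enrichment),
                     n_peaks = n_peaks)
  mz <- c(pair$light$mz, pair$heavy$mz)
  it <- c(light_amt * pair$light$abundance, heavy_amt * pair$heavy$abundance)
  keep <- it > 0
  mz <- mz[keep]; it <- it[keep]
  ord <- order(mz); mz <- mz[ord]; it <- it[ord]
  cl <- cumsum(c(1, diff(mz) > 0.2))
  mzm <- as.numeric(tapply(mz * it, cl, sum) / tapply(it, cl, sum))
  itm <- as.numeric(tapply(it, cl, sum))
  peak_list(mzm, itm, itm)
}
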