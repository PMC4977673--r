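test_that("fixed seeds give byte-identical outputs", {
  cfg <- simulationConfig(seed = 1, nProteins = 10)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  a1 <- tempfile(); a2 <- tempfile(); t1 <- tempfile(); t2 <- tempfile()
  writeSecretome(generateSecretome(cfg), f1, a1, t1, seed = 1)
  writeSecretome(generateSecretome(cfg), f2, a2, t2, seed = 1)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
  expect_equal(unname(tools::md5sum(a1)), unname(tools::md5sum(a2)))
  # evidence and peaks are reproducible too
  sec <- generateSecretome(cfg)
  expect_identical(simulatePeptideEvidence(sec, cfg),
                   simulatePeptideEvidence(sec, cfg))
  expect_identical(simulateGlycanPeaks(cfg), simulateGlycanPeaks(cfg))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generateSecretome(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero density yields sequon-free proteins", {
  cfg <- simulationConfig(seed = 3, nProteins = 10, sequonDensity = 0)
  sec <- generateSecretome(cfg)
  expect_equal(nrow(scanSequons(sec)), 0L)
  expect_equal(nrow(as.data.frame(groundTruth(sec))), 0L)
})

test_that("infeasible densities are rejected", {
  expect_error(simulationConfig(sequonDensity = 40), "infeasible")
})

test_that("planted density is recovered within 3 binomial SE", {
  cfg <- simulationConfig(seed = 1, nProteins = 200,
                          lengthRange = c(200L, 800L), sequonDensity = 1.5)
  sec <- generateSecretome(cfg)
  sites <- scanSequons(sec)
  truth <- as.data.frame(groundTruth(sec))
  # emitted sequon inventory equals the planted one exactly (scrubbing)
  expect_equal(nrow(sites), nrow(truth))
  expect_equal(
    paste(sites$protein_id, sites$position),
    paste(truth$protein_id, truth$position)
  )
  # binomial check under the generator's block-planting model
  q <- 3 * 1.5 / 100
  nBlocks <- sum((Biostrings::width(proteins(sec)) - 2L) %/% 3L)
  se <- sqrt(nBlocks * q * (1 - q))
  expect_lt(abs(nrow(truth) - nBlocks * q), 3 * se)
  # per-100-residue density lands near the target
  dens <- 100 * nrow(truth) / sum(Biostrings::width(proteins(sec)))
  expect_lt(abs(dens - 1.5), 0.3)
})

test_that("boundary coverage/occupancy gives exact evidence", {
  cfg <- simulationConfig(seed = 2, nProteins = 8, coverage = 1,
                          occupancy = 1)
  sec <- generateSecretome(cfg)
  ev <- simulatePeptideEvidence(sec, cfg)
  sites <- scanSequons(sec)
  cov <- mapCoverage(ev, sites)
  expect_true(all(cov$covered))
  # every covering peptide is tagged at every sequon it spans
  for (i in seq_len(nrow(sites))) {
    rows <- as.integer(strsplit(cov$peptide_rows[i], ",")[[1]])
    for (r in rows) {
      mods <- parseModString(ev$mods[r])
      tagAt <- ev$start[r] + mods$position[
        mods$name == "GlcNAc_remnant"
      ] - 1L
      expect_true(sites$position[i] %in% tagAt)
    }
  }
  # zero coverage -> empty table with the full dialect
  cfg0 <- simulationConfig(seed = 2, nProteins = 8, coverage = 0)
  ev0 <- simulatePeptideEvidence(generateSecretome(cfg0), cfg0)
  expect_equal(nrow(ev0), 0L)
  expect_setequal(colnames(ev0), colnames(ev))
})

test_that("emitted peptides are legal tryptic peptides of their protein", {
  cfg <- simulationConfig(seed = 13, nProteins = 10)
  sec <- generateSecretome(cfg)
  ev <- simulatePeptideEvidence(sec, cfg)
  seqs <- as.character(proteins(sec))
  expect_equal(ev$peptide,
               unname(substr(seqs[ev$protein_id], ev$start, ev$end)))
  legal <- unlist(lapply(names(seqs), function(pid) {
    pep <- digestProtein(seqs[pid], maxMissed = 1, proteinId = pid)
    paste(pid, pep$start, pep$end)
  }))
  expect_true(all(paste(ev$protein_id, ev$start, ev$end) %in% legal))
  expect_true(all(ev$spectrum_count > 0))
})

test_that("tagged fraction of covered sites recovers planted occupancy", {
  cfg <- simulationConfig(seed = 41, nProteins = 60, coverage = 1,
                          occupancy = 0.7, sequonDensity = 2)
  sec <- generateSecretome(cfg)
  ev <- simulatePeptideEvidence(sec, cfg)
  cl <- classifySites(scanSequons(sec), ev)
  covered <- cl[cl$status != "non_covered", ]
  n <- nrow(covered)
  expect_gte(n, 500)
  k <- sum(covered$status == "validated")
  # exact binomial 99 % quantile interval around the planted value
  lo <- qbinom(0.005, n, 0.7)
  hi <- qbinom(0.995, n, 0.7)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("glycan peak simulation respects weights and noise settings", {
  # zero noise, single composition -> one exact peak per condition
  w <- setNames(rep(0, 16), paste0("Hex", 3:18))
  w["Hex5"] <- 1
  cfg <- simulationConfig(seed = 4, glycanWeights = w, massErrorSd = 0)
  pool <- simulateGlycanPeaks(cfg)
  expect_equal(nrow(pool$peaks), 3L)   # one per condition
  expect_true(all(abs(pool$peaks$mz - permethylatedMz(5, 2)) < 1e-9))
  # equal weights -> near-equal intensities
  w5 <- setNames(rep(0, 16), paste0("Hex", 3:18))
  w5[paste0("Hex", 5:9)] <- 1
  cfg5 <- simulationConfig(seed = 4, glycanWeights = w5,
                           massErrorSd = 0.01)
  p5 <- simulateGlycanPeaks(cfg5, conditions = "SCB", intensityCv = 0.05)
  expect_equal(nrow(p5$peaks), 5L)
  ratios <- p5$peaks$intensity / mean(p5$peaks$intensity)
  expect_true(all(abs(ratios - 1) < 0.3))
  expect_error(simulationConfig(glycanWeights = rep(0, 16)), "not all zero")
})

test_that("config validity catches out-of-range parameters", {
  expect_error(simulationConfig(occupancy = 1.4), "probabilities")
  expect_error(simulationConfig(lengthRange = c(5L, 50L)), "20")
  expect_error(simulationConfig(massErrorSd = -1), "massErrorSd")
  expect_error(simulationConfig(nProteins = 0), "nProteins")
})
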