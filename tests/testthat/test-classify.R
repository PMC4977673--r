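makeEvidence <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], peptide = r[[2]], start = r[[3]],
               end = r[[4]], mods = r[[5]], spectrum_count = r[[6]],
               condition = r[[7]], stringsAsFactors = FALSE)
  }))
}

test_that("single tagged observation validates a covered site", {
  sites <- scanSequons(c(p = "AAKNATAAK"))   # sequon Asn at 4
  ev <- makeEvidence(
    list("p", "NATAAK", 4L, 9L, "GlcNAc_remnant@1", 1L, "glucose"),
    list("p", "NATAAK", 4L, 9L, "", 50L, "xylan")
  )
  cl <- classifySites(sites, ev)
  expect_equal(cl$status, "validated")
  expect_equal(cl$n_tagged_spectra, 1L)
  # covered but never tagged -> non-glycosylated on this evidence
  cl2 <- classifySites(sites, ev[2, , drop = FALSE])
  expect_equal(cl2$status, "non_validated")
  # no covering peptide at all
  cl3 <- classifySites(sites, ev[0, , drop = FALSE])
  expect_equal(cl3$status, "non_covered")
  # spectral-count weighting and the minimum-tagged filter
  cl4 <- classifySites(sites, ev, minTagged = 2L)
  expect_equal(cl4$status, "non_validated")
  cl5 <- classifySites(sites, makeEvidence(
    list("p", "NATAAK", 4L, 9L, "GlcNAc_remnant@1", 3L, "glucose")
  ), minTagged = 2L, countSpectra = TRUE)
  expect_equal(cl5$status, "validated")
})

test_that("GlcNAc remnant off a sequon Asn is flagged and ignored", {
  sites <- scanSequons(c(p = "AAKNATAAK"))
  ev <- makeEvidence(
    list("p", "AAKNATAAK", 1L, 9L, "GlcNAc_remnant@2", 1L, "glucose")
  )
  expect_warning(cl <- classifySites(sites, ev), "inconsistent")
  expect_equal(cl$status, "non_validated")
})

test_that("boundary occupancies recover the planted truth exactly", {
  cfg1 <- simulationConfig(seed = 5, nProteins = 10, coverage = 1,
                           occupancy = 1)
  sec1 <- generateSecretome(cfg1)
  ev1 <- simulatePeptideEvidence(sec1, cfg1)
  cl1 <- classifySites(scanSequons(sec1), ev1)
  expect_true(all(cl1$status == "validated"))

  cfg0 <- simulationConfig(seed = 5, nProteins = 10, coverage = 1,
                           occupancy = 0)
  sec0 <- generateSecretome(cfg0)
  ev0 <- simulatePeptideEvidence(sec0, cfg0)
  cl0 <- classifySites(scanSequons(sec0), ev0)
  expect_true(all(cl0$status == "non_validated"))
})

test_that("the three classes partition every input", {
  cfg <- simulationConfig(seed = 9, nProteins = 30, coverage = 0.6,
                          occupancy = 0.5)
  sec <- generateSecretome(cfg)
  sites <- scanSequons(sec)
  cl <- classifySites(sites, simulatePeptideEvidence(sec, cfg))
  expect_equal(nrow(cl), nrow(sites))
  counts <- table(factor(cl$status, levels = c("validated", "non_validated",
                                               "non_covered")))
  expect_equal(sum(counts), nrow(sites))
  expect_true(all(cl$status %in% c("validated", "non_validated",
                                   "non_covered")))
})

test_that("adding evidence only promotes, never demotes", {
  cfg <- simulationConfig(seed = 21, nProteins = 15, coverage = 0.5,
                          occupancy = 0.6)
  sec <- generateSecretome(cfg)
  sites <- scanSequons(sec)
  ev <- simulatePeptideEvidence(sec, cfg)
  half <- ev[seq_len(nrow(ev) %/% 2), ]
  rank <- c(non_covered = 0, non_validated = 1, validated = 2)
  before <- rank[classifySites(sites, half)$status]
  after <- rank[classifySites(sites, ev)$status]
  expect_true(all(after >= before))
})

test_that("site summaries render positions and recount correctly", {
  sites <- data.frame(
    protein_id = c("ANID_02828", "ANID_02828", "ANID_02828", "other"),
    position = c(365L, 225L, 340L, 10L),
    sequon_type = "NXT",
    status = c("validated", "validated", "non_covered", "non_validated")
  )
  ann <- data.frame(protein_id = c("ANID_02828", "other"),
                    cazy_family = c("GH3", "non-CAZy"))
  sm <- summarizeSites(sites, ann)
  expect_equal(
    sm$per_protein$validated_positions[
      sm$per_protein$protein_id == "ANID_02828"
    ],
    "225, 365"
  )
  expect_equal(unname(sm$status_counts["validated"]), 2L)
  expect_equal(sm$validated_in_cazy, 2L)
  expect_equal(sm$n_cazy_proteins_validated, 1L)

  # zero validated sites -> all-zero validated summary
  none <- sites
  none$status <- "non_covered"
  sm0 <- summarizeSites(none, ann)
  expect_equal(unname(sm0$status_counts["validated"]), 0L)
  expect_equal(nrow(sm0$per_protein), 0L)

  # recount oracle on a simulated run
  cfg <- simulationConfig(seed = 2, nProteins = 20)
  sec <- generateSecretome(cfg)
  cl <- classifySites(scanSequons(sec), simulatePeptideEvidence(sec, cfg))
  sm <- summarizeSites(cl, as.data.frame(annotations(sec)))
  expect_equal(unname(sm$status_counts),
               unname(vapply(c("validated", "non_validated", "non_covered"),
                             function(s) sum(cl$status == s), integer(1))))
  expect_equal(sm$n_sites, nrow(cl))
})
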