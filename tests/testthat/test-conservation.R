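test_that("site-to-column mapping handles gaps (1-based columns)", {
  gapless <- homologAlignment(c(q = "MKNATAA", h = "MKNATAA"))
  expect_equal(mapSiteToColumn(gapless, 3), 3L)
  # three leading gap columns in the query shift everything right
  shifted <- homologAlignment(c(q = "---MKNATAA", h = "AAAMKNATAA"))
  expect_equal(mapSiteToColumn(shifted, 3), 6L)
  expect_error(mapSiteToColumn(gapless, 99), "outside")
})

test_that("column mapping agrees with a degapped-prefix oracle", {
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(20:80, 1)
    chars <- sample(AA20, n, replace = TRUE)
    gaps <- runif(n) < 0.25
    row <- ifelse(gaps, "-", chars)
    if (all(gaps)) row[1] <- chars[1]
    aln <- homologAlignment(c(q = paste(row, collapse = ""),
                              h = paste(chars, collapse = "")))
    pos <- sample(sum(row != "-"), 1)
    col <- mapSiteToColumn(aln, pos)
    # oracle: the degapped prefix up to that column has length pos
    prefix <- substr(paste(row, collapse = ""), 1, col)
    expect_equal(nchar(gsub("-", "", prefix)), pos)
    expect_true(substr(paste(row, collapse = ""), col, col) != "-")
  }
})

test_that("per-homolog verdicts: identity, destruction, shift tolerance", {
  # identical homolog: conserved with zero offset
  v <- siteConservedIn("MKNATAA", 3, windowTol = 0)
  expect_true(v$conserved)
  expect_equal(v$offset, 0L)
  # sequon destroyed (Asn -> Asp)
  expect_false(siteConservedIn("MKDATAA", 3)$conserved)
  # +2 residue lost
  expect_false(siteConservedIn("MKNAAAA", 3)$conserved)
  # X = P homolog sequon rejected unless allowed
  expect_false(siteConservedIn("MKNPTAA", 3)$conserved)
  expect_true(siteConservedIn("MKNPTAA", 3, allowProlineX = TRUE)$conserved)
  # sequon shifted two columns by an indel: found only at tol >= 2
  row <- "MK--NATAA"   # query site column 3, homolog Asn in column 5
  expect_false(siteConservedIn(row, 3, windowTol = 0)$conserved)
  expect_false(siteConservedIn(row, 3, windowTol = 1)$conserved)
  v2 <- siteConservedIn(row, 3, windowTol = 2)
  expect_true(v2$conserved)
  expect_equal(v2$offset, 2L)
  # verdicts are monotone in the tolerance
  for (tol in 0:4) {
    if (siteConservedIn(row, 3, windowTol = tol)$conserved) {
      expect_true(siteConservedIn(row, 3, windowTol = tol + 1)$conserved)
    }
  }
})

test_that("conservation percentages mirror the homolog-count arithmetic", {
  aln <- conservationFixture(nHom = 20, broken1 = 2, broken2 = 1)
  sites <- data.frame(position = c(11L, 24L))
  cp <- conservationPercent(aln, sites)
  expect_equal(cp$n_homologs, c(20L, 20L))
  expect_equal(cp$n_conserved, c(18L, 19L))
  expect_equal(cp$conservation_pct, c(90.0, 95.0))
})

test_that("conservation is invariant under all-gap column insertion", {
  aln <- conservationFixture()
  rows <- as.character(alignmentRows(aln))
  at <- 15
  padded <- homologAlignment(
    setNames(paste0(substr(rows, 1, at), "---",
                    substr(rows, at + 1, nchar(rows))), names(rows)),
    queryId = "query"
  )
  sites <- data.frame(position = c(11L, 24L))
  expect_equal(conservationPercent(padded, sites)$conservation_pct,
               conservationPercent(aln, sites)$conservation_pct)
})

test_that("simulated families recover the boundary retentions", {
  cfg1 <- simulationConfig(seed = 31, nProteins = 3, homologRetention = 1,
                           indelRate = 0)
  sec <- generateSecretome(cfg1)
  pid <- as.data.frame(groundTruth(sec))$protein_id[1]
  fam <- simulateHomologFamily(sec, pid, 10, cfg1)
  sites <- scanSequons(sec)
  sites <- sites[sites$protein_id == pid, ]
  cp <- conservationPercent(fam$alignment, sites)
  expect_true(all(cp$conservation_pct == 100))
  # homologs identical to the query at sequon columns
  qrow <- as.character(alignmentRows(fam$alignment)[[pid]])
  for (h in setdiff(names(alignmentRows(fam$alignment)), pid)) {
    hrow <- as.character(alignmentRows(fam$alignment)[[h]])
    for (p in sites$position) {
      expect_equal(substr(hrow, p, p + 2), substr(qrow, p, p + 2))
    }
  }

  cfg0 <- simulationConfig(seed = 31, nProteins = 3, homologRetention = 0)
  fam0 <- simulateHomologFamily(sec, pid, 10, cfg0)
  cp0 <- conservationPercent(fam0$alignment, sites)
  expect_true(all(cp0$conservation_pct == 0))
  expect_error(simulateHomologFamily(sec, pid, 0, cfg1), ">= 1")
})

test_that("mean retained count approaches retention * homolog count", {
  cfg <- simulationConfig(seed = 77, nProteins = 1, lengthRange = c(60, 60),
                          sequonDensity = 10, homologRetention = 0.9)
  sec <- generateSecretome(cfg)
  pid <- names(proteins(sec))[1]
  nsites <- nrow(scanSequons(sec))
  expect_gt(nsites, 0)
  draws <- unlist(lapply(1:60, function(r) {
    fam <- simulateHomologFamily(sec, pid, 20, cfg, seed = 1000 + r)
    tapply(fam$retention$retained, fam$retention$position, sum)
  }))
  n <- length(draws) * 20
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(mean(draws) / 20 - 0.9), 3 * se)
})
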