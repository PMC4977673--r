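test_that("the nidulans151 preset has the documented composition", {
  w <- motifPreset("nidulans151")
  expect_length(w, 151)
  expect_true(all(nchar(w) == 13))
  plus1 <- substr(w, 8, 8)
  plus2 <- substr(w, 9, 9)
  expect_equal(sum(plus2 == "T"), 109)
  expect_equal(sum(plus2 == "S"), 42)
  expect_equal(sum(plus1 == "G" & plus2 == "T"), 19)
  expect_equal(sum(plus1 == "T" & plus2 == "T"), 12)
  expect_equal(sum(plus1 == "S" & plus2 == "T"), 14)
  expect_false(any(plus1 == "P"))
  # reproducible, and distinct under another seed
  expect_identical(w, motifPreset("nidulans151"))
  expect_false(identical(w, motifPreset("nidulans151", seed = 2)))
  expect_error(motifPreset("unknown"), "unknown preset")
})

test_that("motif report equals a brute-force pattern count", {
  set.seed(19)
  motifs <- c("......n.T....", "......n.S....", "......nGT....",
              "A.....n......", "......n....KK")
  for (rep in 1:5) {
    w <- randomWindows(200)
    # inject some padded windows
    substr(w[1:10], 1, 2) <- "--"
    rep_tab <- motifReport(w, motifs)
    for (i in seq_along(motifs)) {
      expect_equal(rep_tab$dataset_matches[i],
                   bruteForceMotifCount(w, motifs[i]))
    }
    # the exhaustive sequon pair sums to 100 before rounding when every
    # window ends in S or T at +2
    w2 <- motifPreset("nidulans151")
    r2 <- motifReport(w2, c("......n.T....", "......n.S...."))
    expect_equal(sum(r2$dataset_pct_exact), 100)
  }
})

test_that("display rounding reproduces the one-decimal style", {
  w <- motifPreset("nidulans151")
  r <- motifReport(w, c("......n.T....", "......n.S....", "......nGT....",
                        "......nST....", "......nTT...."))
  expect_equal(r$dataset_pct, c(72.2, 27.8, 12.6, 9.3, 7.9))
})

test_that("background percentages count Asn-centred windows", {
  # single-Asn background: its one window matches n.T
  r <- motifReport(randomWindows(5), "......n.T....",
                   background = c(b = "AANATAA"))
  expect_equal(r$background_pct, 100)
  # a background with 2 Asn windows, one matching
  r2 <- motifReport(randomWindows(5), "......n.T....",
                    background = c(b = "AANATAANAWAA"))
  expect_equal(r2$background_pct, 50)
  expect_equal(r2$fold_enrichment, r2$dataset_pct_exact / 50)
  # pads never match residue letters or '.'
  r3 <- motifReport(c("------nAT----"), "T.....n.T....")
  expect_equal(r3$dataset_matches, 0L)
  expect_error(motifReport(character(), "......n.T...."), "empty")
})

test_that("sequon preference proportions are exact counts", {
  sites <- data.frame(sequon_type = rep("NXT", 5), status = "validated")
  pref <- sequonPreference(sites)
  expect_equal(pref$pct_NXT, 100)
  expect_equal(pref$pct_NXS, 0)
  # planted 60/40 split recovered exactly
  sites2 <- data.frame(
    sequon_type = c(rep("NXT", 600), rep("NXS", 400)),
    status = sample(c("validated", "non_validated"), 1000, replace = TRUE)
  )
  sites2$sequon_type <- sample(sites2$sequon_type)
  all2 <- sequonPreference(transform(sites2, status = "validated"))
  expect_equal(all2$pct_NXT, 60)
  expect_equal(all2$pct_NXS, 40)
  expect_equal(all2$pct_NXT + all2$pct_NXS, 100)
})

test_that("chemical-class profile excludes sequon positions and pads", {
  alaWin <- vapply(1:20, function(i) {
    w <- rep("A", 13); w[7] <- "n"; paste(w, collapse = "")
  }, character(1))
  prof <- flankingClassProfile(alaWin)
  expect_false(any(prof$position %in% c(0, 2)))
  expect_equal(nrow(prof), 11)
  expect_true(all(prof$Hydrophobic == 1))
  glyWin <- gsub("A", "G", alaWin)
  expect_true(all(flankingClassProfile(glyWin)$Unique == 1))
  # frequencies sum to 1 over non-pad residues
  set.seed(4)
  w <- randomWindows(500)
  substr(w[1:50], 1, 3) <- "---"
  prof <- flankingClassProfile(w)
  classCols <- names(chemicalClasses())
  expect_true(all(abs(rowSums(prof[classCols]) - 1) < 1e-12))
  expect_true(all(prof$n_residues[prof$position %in% (-6:-4)] == 450))
})

test_that("uniform windows give class frequencies near class size / 20", {
  set.seed(8)
  w <- randomWindows(10000)
  prof <- flankingClassProfile(w)
  for (cl in names(chemicalClasses())) {
    p <- length(chemicalClasses()[[cl]]) / 20
    se <- sqrt(p * (1 - p) / 10000)
    expect_true(all(abs(prof[[cl]] - p) < 3.5 * se))
  }
})

test_that("greedy motif search finds a strongly planted motif", {
  set.seed(13)
  w <- randomWindows(120)
  substr(w[1:80], 8, 9) <- "GT"   # plant nGT in two thirds of the windows
  bg <- setNames(vapply(1:20, function(i) randomProtein(400), character(1)),
                 paste0("b", 1:20))
  found <- motifSearch(w, bg, alpha = 1e-3)
  expect_true(any(grepl("^......nGT", found)))
})
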