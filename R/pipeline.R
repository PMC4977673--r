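## End-to-end orchestration. Stages run in dependency order on simulated or
## pre-existing inputs and write plain-text outputs plus a JSON run manifest
## (config snapshot, seed, file checksums), so a fixed config + seed is
## bitwise-reproducible modulo timestamps.

.PIPELINE_STAGES <- c("simulate", "scan", "classify", "motifs", "conserve",
                      "glycans", "summarize")

#' Run the N-glycosylation mapping pipeline
#'
#' Executes the stages in dependency order: simulate (generate secretome,
#' peptide evidence, homolog families, glycan peaks), scan (sequon
#' inventory), classify (three-class evidence partition + summary), motifs
#' (motif report, sequon preference, chemical-class profile), conserve
#' (per-site conservation over simulated families), glycans (composition
#' assignment + hexose distribution), summarize (detection overlaps, family
#' proportions, top proteins). Omitting a stage from \code{stages} skips it
#' and its outputs; downstream stages that need it are skipped too.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if needed).
#' @param stages subset of \code{c("simulate", "scan", "classify",
#'   "motifs", "conserve", "glycans", "summarize")}; "simulate" is always
#'   implied. Default: all.
#' @param nFamilies homolog families simulated for the conservation stage.
#' @param nHomologs homolog rows per family.
#' @param motifs motif patterns for the report (default: the sequon split
#'   and its common X-position variants).
#' @param verbose log stage timings to stderr.
#' @return Invisible list with all stage results plus \code{manifest}.
#' @export
runPipeline <- function(config, outDir,
                        stages = .PIPELINE_STAGES,
                        nFamilies = 5L, nHomologs = 20L,
                        motifs = c("......n.T....", "......n.S....",
                                   "......nGT....", "......nST....",
                                   "......nTT...."),
                        verbose = FALSE) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- union("simulate", stages)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[glycoMapper] ", ...)
  results <- list()
  files <- character()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## --- simulate -----------------------------------------------------
  secretome <- generateSecretome(config)
  evidence <- simulatePeptideEvidence(secretome, config)
  fasta <- file.path(outDir, "proteins.fasta")
  writeSecretome(secretome, fasta,
                 file.path(outDir, "annotations.tsv"),
                 file.path(outDir, "truth_sites.tsv"), seed = config@seed)
  writeTsv(evidence, file.path(outDir, "evidence.tsv"), comments = c(
    "peptide evidence; 1-based inclusive coordinates",
    "mods: ';'-joined name@position (position within peptide)",
    paste("simulation seed:", config@seed)
  ))
  files <- c(files, "proteins.fasta", "annotations.tsv", "truth_sites.tsv",
             "evidence.tsv")
  results$secretome <- secretome
  results$evidence <- evidence
  say("simulate done (", round(tic() - t0, 2), "s)")

  ## --- scan ---------------------------------------------------------
  if ("scan" %in% stages) {
    sites <- scanSequons(secretome)
    writeTsv(sites, file.path(outDir, "sites.tsv"), comments = c(
      "predicted sequon sites; 1-based Asn positions",
      "window: -6..+6, '-'-padded, centre rendered 'n'"
    ))
    files <- c(files, "sites.tsv")
    results$sites <- sites
  }

  ## --- classify -----------------------------------------------------
  if (all(c("scan", "classify") %in% stages)) {
    classified <- classifySites(results$sites, evidence)
    summary <- summarizeSites(classified,
                              as.data.frame(annotations(secretome)))
    writeTsv(
      classified[setdiff(colnames(classified), "peptide_rows")],
      file.path(outDir, "classified_sites.tsv"),
      comments = "site status: validated / non_validated / non_covered"
    )
    jsonlite::write_json(
      summary[c("status_counts", "n_sites", "validated_in_cazy",
                "n_cazy_proteins_validated")],
      file.path(outDir, "site_summary.json"), auto_unbox = TRUE
    )
    files <- c(files, "classified_sites.tsv", "site_summary.json")
    results$classified <- classified
    results$site_summary <- summary
  }

  ## --- motifs -------------------------------------------------------
  if (all(c("classify", "motifs") %in% stages)) {
    valWindows <- results$classified$window[
      results$classified$status == "validated"
    ]
    if (length(valWindows)) {
      report <- motifReport(valWindows, motifs, background = secretome)
      writeTsv(report, file.path(outDir, "motif_report.tsv"), comments =
        paste("motif report over", length(valWindows),
              "validated-site windows"))
      profile <- flankingClassProfile(valWindows)
      writeTsv(profile, file.path(outDir, "class_profile.tsv"),
               comments = "positions 0 and +2 excluded (fixed by sequon)")
      pref <- sequonPreference(results$classified)
      writeTsv(pref, file.path(outDir, "sequon_preference.tsv"))
      files <- c(files, "motif_report.tsv", "class_profile.tsv",
                 "sequon_preference.tsv")
      results$motif_report <- report
      results$class_profile <- profile
      results$sequon_preference <- pref
    }
  }

  ## --- conserve -----------------------------------------------------
  if (all(c("scan", "conserve") %in% stages)) {
    withSites <- unique(results$sites$protein_id)
    pick <- utils::head(withSites, nFamilies)
    cons <- lapply(pick, function(pid) {
      fam <- simulateHomologFamily(secretome, pid, nHomologs, config)
      cp <- conservationPercent(
        fam$alignment,
        results$sites[results$sites$protein_id == pid, , drop = FALSE]
      )
      cp$protein_id <- pid
      cp[c("protein_id", setdiff(colnames(cp), c("protein_id", "offsets")))]
    })
    cons <- do.call(rbind, cons)
    writeTsv(cons, file.path(outDir, "conservation.tsv"), comments =
      "per-site conservation over simulated homolog families; tol 0")
    files <- c(files, "conservation.tsv")
    results$conservation <- cons
  }

  ## --- glycans ------------------------------------------------------
  if ("glycans" %in% stages) {
    pool <- simulateGlycanPeaks(config)
    writeTsv(pool$peaks, file.path(outDir, "glycan_peaks.tsv"), comments =
      "permethylated sodiated [M+Na]+ peaks; monoisotopic m/z")
    assigned <- assignCompositions(pool$peaks)
    writeTsv(assigned, file.path(outDir, "glycan_assignments.tsv"))
    dist <- hexoseDistribution(assigned)
    writeTsv(dist$proportions,
             file.path(outDir, "hexose_distribution.tsv"),
             comments = "intensity-weighted proportions per condition")
    files <- c(files, "glycan_peaks.tsv", "glycan_assignments.tsv",
               "hexose_distribution.tsv")
    results$glycans <- list(peaks = pool, assigned = assigned,
                            distribution = dist)
  }

  ## --- summarize ----------------------------------------------------
  if ("summarize" %in% stages) {
    dt <- detectionTable(evidence)
    overlap <- conditionOverlap(dt)
    writeTsv(dt, file.path(outDir, "detection_table.tsv"))
    writeTsv(overlap$regions, file.path(outDir, "condition_overlap.tsv"))
    props <- classFamilyProportions(
      dt, as.data.frame(annotations(secretome))
    )
    writeTsv(props$full, file.path(outDir, "family_proportions.tsv"))
    top <- topProteins(dt, as.data.frame(annotations(secretome)))
    writeTsv(top, file.path(outDir, "top_proteins.tsv"))
    files <- c(files, "detection_table.tsv", "condition_overlap.tsv",
               "family_proportions.tsv", "top_proteins.tsv")
    results$detection <- dt
    results$overlap <- overlap
    results$family_proportions <- props
    results$top_proteins <- top
  }

  ## --- manifest -----------------------------------------------------
  paths <- file.path(outDir, files)
  manifest <- list(
    package = "glycoMapper",
    version = as.character(utils::packageVersion("glycoMapper")),
    seed = config@seed,
    config = .configAsList(config),
    stages = stages,
    outputs = data.frame(
      file = files,
      md5 = unname(tools::md5sum(paths)),
      stringsAsFactors = FALSE
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  say("pipeline done (", round(tic() - t0, 2), "s)")
  invisible(results)
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}
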