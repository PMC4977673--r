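## Synthetic-secretome generator. Every downstream stage can be exercised
## against known ground truth: planted sequon positions and occupancy,
## homolog retention draws, and glycan pool composition. One RNG stream per
## generator entry point, derived from the config seed, so fixed seeds give
## byte-identical outputs.

# CAZy family pool used for annotation labels, with the functional groups
# used by the top-protein summaries.
.CAZY_POOL <- data.frame(
  family = c("GH7", "GH6", "GH5", "GH3", "GH10", "GH11", "GH43", "GH62",
             "GH28", "GH81", "AA9", "AA8", "AA7", "AA1", "CE1", "CE5",
             "CE16", "PL1", "PL4", "CBM1"),
  group = c("cellulases", "cellulases", "cellulases", "cellulases",
            "hemicellulases", "hemicellulases", "hemicellulases",
            "hemicellulases", "pectinases", "cellulases", "oxidases",
            "oxidases", "oxidases", "oxidases", "esterases", "esterases",
            "esterases", "pectinases", "pectinases", "CBMs"),
  stringsAsFactors = FALSE
)

# run the generator body under a seed derived from the config stream,
# restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Generate a synthetic secretome with known ground truth
#'
#' Simulates secreted proteins as uniform-random sequences over the 20
#' standard residues with N-X-S/T sequons planted by substitution. Candidate
#' anchors sit at the starts of consecutive 3-residue blocks; each is
#' planted independently with probability \code{3 * sequonDensity / 100}, so
#' the expected density is \code{sequonDensity} per 100 residues and the
#' planted count is binomial over blocks. Accidental background sequons are
#' scrubbed (their +2 Ser/Thr rewritten to Ala, which can only destroy
#' sequons), so the emitted sequon inventory equals the planted one exactly.
#' Each planted site receives a ground-truth occupancy label with
#' probability \code{occupancy}. Proteins are assigned a CAZy family label
#' (or "non-CAZy") and a secretion flag.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param pCazy probability a protein is CAZy-annotated (default 0.7).
#' @return A \linkS4class{Secretome}; \code{groundTruth()} holds the planted
#'   site table (\code{protein_id}, \code{position}, \code{sequon_type},
#'   \code{occupied}).
#' @examples
#' sec <- generateSecretome(simulationConfig(seed = 1, nProteins = 5))
#' sec
#' @export
generateSecretome <- function(config, pCazy = 0.7) {
  validObject(config)
  .withSeed(config@seed, {
    q <- 3 * config@sequonDensity / 100
    ids <- sprintf("SIM_%05d", seq_len(config@nProteins))
    seqs <- character(config@nProteins)
    truth <- vector("list", config@nProteins)
    for (i in seq_len(config@nProteins)) {
      L <- config@lengthRange[1] +
        sample.int(config@lengthRange[2] - config@lengthRange[1] + 1L, 1L) -
        1L
      chars <- sample(.AMINO_ACIDS, L, replace = TRUE)
      nBlocks <- (L - 2L) %/% 3L
      anchors <- integer()
      if (nBlocks > 0L && q > 0) {
        planted <- which(runif(nBlocks) < q)
        anchors <- 3L * (planted - 1L) + 1L
        for (a in anchors) {
          chars[a] <- "N"
          if (chars[a + 1L] == "P") {
            chars[a + 1L] <- sample(setdiff(.AMINO_ACIDS, "P"), 1L)
          }
          chars[a + 2L] <- sample(c("S", "T"), 1L)
        }
      }
      chars <- .scrubAccidentalSequons(chars, anchors)
      seqs[i] <- paste(chars, collapse = "")
      if (length(anchors)) {
        truth[[i]] <- data.frame(
          protein_id = ids[i],
          position = anchors,
          sequon_type = ifelse(chars[anchors + 2L] == "T", "NXT", "NXS"),
          occupied = runif(length(anchors)) < config@occupancy,
          stringsAsFactors = FALSE
        )
      }
    }
    isCazy <- runif(config@nProteins) < pCazy
    fam <- ifelse(
      isCazy,
      sample(.CAZY_POOL$family, config@nProteins, replace = TRUE),
      "non-CAZy"
    )
    ann <- DataFrame(
      protein_id = ids,
      cazy_family = fam,
      secreted = runif(config@nProteins) < 0.95,
      group = ifelse(
        fam == "non-CAZy", "other",
        .CAZY_POOL$group[match(fam, .CAZY_POOL$family)]
      )
    )
    truth <- do.call(rbind, truth)
    if (is.null(truth)) {
      truth <- data.frame(
        protein_id = character(), position = integer(),
        sequon_type = character(), occupied = logical(),
        stringsAsFactors = FALSE
      )
    }
    sequences <- Biostrings::AAStringSet(setNames(seqs, ids))
    new("Secretome", sequences = sequences, annotations = ann,
        truth = DataFrame(truth))
  })
}

# destroy every sequon not anchored at a planted position by rewriting its
# +2 S/T to 'A' (cannot create new sequons: only S/T -> A substitutions)
.scrubAccidentalSequons <- function(chars, anchors) {
  repeat {
    s <- paste(chars, collapse = "")
    m <- gregexpr("N(?=.[ST])", s, perl = TRUE)[[1]]
    found <- if (m[1] == -1L) integer() else as.integer(m)
    rogue <- setdiff(found, anchors)
    if (!length(rogue)) return(chars)
    chars[rogue + 2L] <- "A"
  }
}

#' Simulate tryptic peptide evidence
#'
#' Emits observed tryptic peptides of each secretome protein in the dialect
#' the classifier consumes. Every zero-missed peptide is observed with
#' probability \code{coverage}; an observed peptide retains one missed
#' cleavage (is replaced by its join with the next fragment) with
#' probability \code{missedCleavageRate}. Peptides covering an occupied
#' sequon carry the +203 GlcNAc remnant on the sequon Asn; cysteines carry
#' fixed carbamidomethyl; methionines are variably oxidised at a small
#' background rate. Spectrum counts are drawn per condition from a
#' Poisson-gamma (negative binomial) model around a per-protein,
#' per-condition abundance.
#'
#' @param secretome a \linkS4class{Secretome} from
#'   \code{\link{generateSecretome}}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @param conditions condition names (default "glucose", "SCB", "xylan",
#'   extended as "cond<k>" beyond three).
#' @param oxidationRate per-Met variable oxidation probability.
#' @return Evidence data.frame: \code{protein_id}, \code{peptide},
#'   \code{start}, \code{end}, \code{mods} (";"-joined "name@position"),
#'   \code{spectrum_count}, \code{condition}. One row per observed peptide
#'   per condition with nonzero count.
#' @export
simulatePeptideEvidence <- function(secretome, config,
                                    conditions = NULL,
                                    oxidationRate = 0.05) {
  validObject(config)
  if (is.null(conditions)) {
    base <- c("glucose", "SCB", "xylan")
    conditions <- if (config@nConditions <= 3L) {
      base[seq_len(config@nConditions)]
    } else {
      c(base, paste0("cond", 4:config@nConditions))
    }
  }
  truth <- as.data.frame(groundTruth(secretome))
  seqs <- as.character(proteins(secretome))
  .withSeed(config@seed + 1L, {
    out <- vector("list", length(seqs))
    size <- if (config@abundanceDispersion > 0) {
      1 / config@abundanceDispersion
    } else {
      Inf
    }
    for (i in seq_along(seqs)) {
      pid <- names(seqs)[i]
      pep0 <- digestProtein(seqs[i], maxMissed = 0L, proteinId = pid)
      k <- nrow(pep0)
      if (!k) next
      observed <- which(runif(k) < config@coverage)
      if (!length(observed)) next
      joinNext <- runif(length(observed)) < config@missedCleavageRate
      st <- pep0$start[observed]
      en <- pep0$end[observed]
      canJoin <- joinNext & observed < k
      en[canJoin] <- pep0$end[observed[canJoin] + 1L]
      mc <- as.integer(canJoin)
      pepSeq <- substr(rep(seqs[i], length(st)), st, en)
      occ <- truth[truth$protein_id == pid & truth$occupied, , drop = FALSE]
      # per-protein, per-condition abundance on a log scale
      mu <- exp(rnorm(length(conditions), mean = 1.2, sd = 1))
      mods <- character(length(st))
      for (j in seq_along(st)) {
        pchars <- strsplit(pepSeq[j], "")[[1]]
        mm <- character()
        cpos <- which(pchars == "C")
        if (length(cpos)) mm <- paste0("carbamidomethyl@", cpos)
        mpos <- which(pchars == "M")
        if (length(mpos)) {
          ox <- mpos[runif(length(mpos)) < oxidationRate]
          if (length(ox)) mm <- c(mm, paste0("oxidation@", ox))
        }
        if (nrow(occ)) {
          hit <- occ$position[occ$position >= st[j] & occ$position <= en[j]]
          if (length(hit)) {
            mm <- c(mm, paste0("GlcNAc_remnant@", hit - st[j] + 1L))
          }
        }
        mods[j] <- paste(mm, collapse = ";")
      }
      counts <- lapply(seq_along(conditions), function(ci) {
        n <- if (is.finite(size)) {
          rnbinom(length(st), size = size, mu = mu[ci])
        } else {
          stats::rpois(length(st), mu[ci])
        }
        data.frame(
          protein_id = pid, peptide = pepSeq, start = st, end = en,
          mods = mods, spectrum_count = n, condition = conditions[ci],
          stringsAsFactors = FALSE
        )
      })
      counts <- do.call(rbind, counts)
      # an observed peptide is one that was identified at least once
      key <- paste(counts$start, counts$end)
      seen <- tapply(counts$spectrum_count, key, sum)
      zero <- names(seen)[seen == 0]
      if (length(zero)) {
        bump <- key %in% zero & counts$condition == conditions[1]
        counts$spectrum_count[bump] <- 1L
      }
      out[[i]] <- counts[counts$spectrum_count > 0, , drop = FALSE]
    }
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(
        protein_id = character(), peptide = character(), start = integer(),
        end = integer(), mods = character(), spectrum_count = integer(),
        condition = character(), stringsAsFactors = FALSE
      )
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate a homolog family alignment
#'
#' Builds an aligned family around one query protein: homologs are mutated
#' copies in which each query sequon is independently retained with
#' probability \code{homologRetention} (non-retained sequons have their Asn
#' substituted), non-sequon columns are substituted at a background rate,
#' and deletions are introduced per column at \code{indelRate} without
#' touching retained sequon columns.
#'
#' @param secretome a \linkS4class{Secretome} (or any object accepted by
#'   \code{\link{scanSequons}}).
#' @param proteinId id of the query protein; must contain >= 1 sequon.
#' @param nHomologs number of homolog rows (>= 1).
#' @param config a \linkS4class{SimulationConfig}.
#' @param substitutionRate per-residue background substitution probability.
#' @param seed RNG seed; defaults to a stream derived from the config seed
#'   and the protein id, so families are reproducible independently of call
#'   order.
#' @return List: \code{alignment} (a \linkS4class{HomologAlignment}) and
#'   \code{retention} (data.frame: \code{homolog}, \code{position},
#'   \code{retained} — the ground-truth draws).
#' @export
simulateHomologFamily <- function(secretome, proteinId, nHomologs, config,
                                  substitutionRate = 0.05, seed = NULL) {
  validObject(config)
  if (nHomologs < 1L) stop("nHomologs must be >= 1")
  seqs <- .asSequenceVector(secretome)
  if (!proteinId %in% names(seqs)) stop("unknown protein: ", proteinId)
  qseq <- seqs[[proteinId]]
  sites <- scanSequons(seqs[proteinId])
  if (!nrow(sites)) stop("query protein has no sequon")
  if (is.null(seed)) {
    seed <- config@seed + 2L +
      sum(utf8ToInt(proteinId)) %% 100003L
  }
  .withSeed(seed, {
    qchars <- strsplit(qseq, "")[[1]]
    L <- length(qchars)
    sequonCols <- unique(unlist(lapply(sites$position, function(p) {
      p:(p + 2L)
    })))
    rows <- list()
    rows[[proteinId]] <- qchars
    retention <- list()
    for (h in seq_len(nHomologs)) {
      hid <- sprintf("%s_hom%02d", proteinId, h)
      hc <- qchars
      # background substitutions outside sequon columns
      subIdx <- which(runif(L) < substitutionRate)
      subIdx <- setdiff(subIdx, sequonCols)
      if (length(subIdx)) {
        hc[subIdx] <- vapply(hc[subIdx], function(r) {
          sample(setdiff(.AMINO_ACIDS, r), 1L)
        }, character(1))
      }
      retained <- runif(nrow(sites)) < config@homologRetention
      for (s in which(!retained)) {
        p <- sites$position[s]
        hc[p] <- sample(setdiff(.AMINO_ACIDS, "N"), 1L)
      }
      # deletions (gaps) at the configured rate, sparing retained sequons
      keepCols <- unique(unlist(lapply(
        sites$position[retained], function(p) p:(p + 2L)
      )))
      gapIdx <- which(runif(L) < config@indelRate)
      gapIdx <- setdiff(gapIdx, keepCols)
      if (length(gapIdx)) hc[gapIdx] <- "-"
      rows[[hid]] <- hc
      retention[[h]] <- data.frame(
        homolog = hid, position = sites$position, retained = retained,
        stringsAsFactors = FALSE
      )
    }
    aln <- Biostrings::AAStringSet(
      vapply(rows, paste, character(1), collapse = "")
    )
    list(
      alignment = homologAlignment(aln, queryId = proteinId),
      retention = do.call(rbind, retention)
    )
  })
}

#' Simulate a MALDI peak list of permethylated N-glycans
#'
#' One peak per nonzero composition (HexNAc fixed at 2) per condition, at
#' the theoretical sodiated permethylated m/z plus Gaussian error, with
#' intensity proportional to the pool weight under multiplicative
#' log-normal noise. The default per-condition weights emulate the study
#' design: a Hex5-dominant pool in glucose and SCB (with trace Hex14..Hex17
#' in glucose only) and a flat Hex5..Hex9 pool in xylan.
#'
#' @param config a \linkS4class{SimulationConfig}. When
#'   \code{config@glycanWeights} differs from
#'   \code{\link{defaultGlycanWeights}}, that single pool is used for every
#'   condition.
#' @param conditions condition names (default "glucose", "SCB", "xylan").
#' @param intensityCv coefficient of variation of the multiplicative
#'   intensity noise.
#' @return List: \code{peaks} (data.frame \code{mz}, \code{intensity},
#'   \code{condition}) and \code{truth} (data.frame \code{condition},
#'   \code{n_hex}, \code{proportion} — the planted pool proportions).
#' @export
simulateGlycanPeaks <- function(config, conditions = c("glucose", "SCB",
                                                       "xylan"),
                                intensityCv = 0.1) {
  validObject(config)
  custom <- !isTRUE(all.equal(config@glycanWeights, defaultGlycanWeights()))
  pools <- lapply(conditions, function(cond) {
    if (custom) return(config@glycanWeights)
    w <- defaultGlycanWeights()
    if (cond == "xylan") {
      w[] <- 0
      w[paste0("Hex", 5:9)] <- 0.2
    } else if (cond == "glucose") {
      w[paste0("Hex", 14:17)] <- 0.002
      w <- w / sum(w)
    }
    w
  })
  names(pools) <- conditions
  .withSeed(config@seed + 3L, {
    peaks <- list()
    truth <- list()
    for (cond in conditions) {
      w <- pools[[cond]]
      nz <- which(w > 0)
      hexCounts <- as.integer(sub("Hex", "", names(w)[nz]))
      mz <- permethylatedMz(hexCounts, 2L) +
        rnorm(length(nz), sd = config@massErrorSd)
      intensity <- w[nz] * exp(rnorm(length(nz), sd = intensityCv)) * 1e4
      peaks[[cond]] <- data.frame(
        mz = mz, intensity = as.numeric(intensity), condition = cond,
        stringsAsFactors = FALSE
      )
      truth[[cond]] <- data.frame(
        condition = cond, n_hex = hexCounts,
        proportion = as.numeric(w[nz] / sum(w[nz])),
        stringsAsFactors = FALSE
      )
    }
    list(
      peaks = do.call(rbind, c(peaks, make.row.names = FALSE)),
      truth = do.call(rbind, c(truth, make.row.names = FALSE))
    )
  })
}

#' Flanking-window presets
#'
#' \code{"nidulans151"} reproduces the composition of the 151-window
#' validated-site dataset of the A. nidulans secretome study this package
#' emulates: 42 N-X-S and 109 N-X-T windows, of which 19 carry Gly, 12 Thr
#' and 14 Ser at the X (+1) position. Unconstrained positions are filled
#' uniformly at random under a fixed seed; windows are treated as unique
#' sites.
#'
#' @param name preset name; only \code{"nidulans151"} is defined.
#' @param seed RNG seed for the unconstrained positions (fixed default so
#'   the preset is reproducible).
#' @return Character vector of 151 13-character windows.
#' @examples
#' length(motifPreset("nidulans151"))
#' @export
motifPreset <- function(name = "nidulans151", seed = 151L) {
  if (!identical(name, "nidulans151")) stop("unknown preset: ", name)
  .withSeed(seed, {
    nonP <- setdiff(.AMINO_ACIDS, "P")
    xOther <- setdiff(nonP, c("G", "T", "S"))
    xs <- c(
      rep("G", 19), rep("T", 12), rep("S", 14),
      sample(xOther, 109 - 19 - 12 - 14, replace = TRUE)
    )
    plus2 <- c(rep("T", 109), rep("S", 42))
    xs <- c(xs, sample(nonP, 42, replace = TRUE))
    vapply(seq_len(151), function(i) {
      flank <- sample(.AMINO_ACIDS, 13, replace = TRUE)
      flank[7] <- "n"
      flank[8] <- xs[i]
      flank[9] <- plus2[i]
      paste(flank, collapse = "")
    }, character(1))
  })
}
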