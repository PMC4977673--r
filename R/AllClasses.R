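#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats rbinom rnbinom rnorm runif setNames quantile binom.test
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic-secretome generator. The defaults describe the
#' study design the package emulates: a filamentous-fungus secretome grown on
#' three carbon sources, protein-level glycopeptide enrichment, tryptic
#' digestion with one allowed missed cleavage, and a high-mannose glycan pool
#' dominated by Hex5HexNAc2.
#'
#' @slot seed integer; RNG seed recorded in all outputs.
#' @slot nProteins integer; number of simulated secreted proteins.
#' @slot lengthRange integer(2); protein length bounds (residues), min >= 20.
#' @slot sequonDensity numeric; expected sequons per 100 residues.
#' @slot occupancy numeric in [0,1]; probability a planted sequon is truly
#'   glycosylated.
#' @slot coverage numeric in [0,1]; probability a tryptic peptide is observed.
#' @slot missedCleavageRate numeric in [0,1]; probability an observed peptide
#'   retains one missed cleavage.
#' @slot nConditions integer; number of growth conditions.
#' @slot abundanceDispersion numeric >= 0; overdispersion of spectrum counts
#'   (negative-binomial size = 1/dispersion).
#' @slot homologRetention numeric in [0,1]; probability a homolog retains a
#'   query sequon.
#' @slot indelRate numeric in [0,1]; per-column gap probability in simulated
#'   alignments.
#' @slot glycanWeights named numeric; relative abundance per Hex count
#'   (Hex3..Hex18), nonnegative, not all zero.
#' @slot massErrorSd numeric >= 0; Gaussian m/z error (Da) on simulated peaks.
#'
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  nProteins = "integer",
  lengthRange = "integer",
  sequonDensity = "numeric",
  occupancy = "numeric",
  coverage = "numeric",
  missedCleavageRate = "numeric",
  nConditions = "integer",
  abundanceDispersion = "numeric",
  homologRetention = "numeric",
  indelRate = "numeric",
  glycanWeights = "numeric",
  massErrorSd = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p01 <- c(
    occupancy = object@occupancy, coverage = object@coverage,
    missedCleavageRate = object@missedCleavageRate,
    homologRetention = object@homologRetention, indelRate = object@indelRate
  )
  bad <- p01 < 0 | p01 > 1
  if (any(bad)) {
    msg <- c(msg, paste0(
      "probabilities must lie in [0,1]: ",
      paste(names(p01)[bad], collapse = ", ")
    ))
  }
  if (length(object@lengthRange) != 2L || object@lengthRange[1] < 20L) {
    msg <- c(msg, "lengthRange must be two integers with min >= 20")
  }
  if (diff(object@lengthRange) < 0) {
    msg <- c(msg, "lengthRange must be nondecreasing")
  }
  if (object@sequonDensity < 0) msg <- c(msg, "sequonDensity must be >= 0")
  if (object@sequonDensity > 100 / 3) {
    msg <- c(msg, paste(
      "sequonDensity too high: sequons span 3 residues, so planting is",
      "infeasible above 100/3 per 100 residues"
    ))
  }
  if (any(object@glycanWeights < 0) || all(object@glycanWeights == 0)) {
    msg <- c(msg, "glycanWeights must be nonnegative and not all zero")
  }
  if (object@massErrorSd < 0) msg <- c(msg, "massErrorSd must be >= 0")
  if (object@abundanceDispersion < 0) {
    msg <- c(msg, "abundanceDispersion must be >= 0")
  }
  if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
  if (object@nConditions < 1L) msg <- c(msg, "nConditions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed RNG seed (integer).
#' @param nProteins number of proteins to simulate.
#' @param lengthRange protein length range in residues, minimum 20.
#' @param sequonDensity expected sequons per 100 residues. Sequons occupy
#'   three residues, so densities above 100/3 are rejected as infeasible.
#' @param occupancy probability a planted sequon is truly glycosylated.
#' @param coverage probability each tryptic peptide is observed.
#' @param missedCleavageRate probability an observed peptide retains one
#'   missed cleavage.
#' @param nConditions number of growth conditions (default 3: glucose, SCB,
#'   xylan).
#' @param abundanceDispersion spectrum-count overdispersion; counts are drawn
#'   from a Poisson-gamma (negative binomial) model with size =
#'   1/dispersion.
#' @param homologRetention probability a homolog retains each query sequon.
#' @param indelRate per-column gap probability in simulated homologs.
#' @param glycanWeights named numeric vector of relative abundances for
#'   Hex3..Hex18 (names "Hex3".."Hex18"); the default is a Hex5-dominant
#'   high-mannose pool.
#' @param massErrorSd Gaussian mass error (Da) added to simulated peaks.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nProteins = 10)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nProteins = 50L,
                             lengthRange = c(200L, 800L),
                             sequonDensity = 1.5,
                             occupancy = 0.7,
                             coverage = 0.8,
                             missedCleavageRate = 0.1,
                             nConditions = 3L,
                             abundanceDispersion = 0.5,
                             homologRetention = 0.9,
                             indelRate = 0.02,
                             glycanWeights = defaultGlycanWeights(),
                             massErrorSd = 0.05) {
  new("SimulationConfig",
    seed = as.integer(seed), nProteins = as.integer(nProteins),
    lengthRange = as.integer(lengthRange), sequonDensity = sequonDensity,
    occupancy = occupancy, coverage = coverage,
    missedCleavageRate = missedCleavageRate,
    nConditions = as.integer(nConditions),
    abundanceDispersion = abundanceDispersion,
    homologRetention = homologRetention, indelRate = indelRate,
    glycanWeights = glycanWeights, massErrorSd = massErrorSd
  )
}

#' Default high-mannose glycan pool weights
#'
#' Relative abundances over Hex3..Hex18 (HexNAc fixed at 2) describing a
#' Hex5-dominant high-mannose pool with decreasing abundance up to Hex9 and
#' trace species beyond, the profile typical of Aspergillus secretomes.
#'
#' @return Named numeric vector ("Hex3".."Hex18") summing to 1.
#' @export
defaultGlycanWeights <- function() {
  w <- c(
    Hex3 = 0.02, Hex4 = 0.08, Hex5 = 0.40, Hex6 = 0.18, Hex7 = 0.14,
    Hex8 = 0.09, Hex9 = 0.06, Hex10 = 0.01, Hex11 = 0.005, Hex12 = 0.005,
    Hex13 = 0, Hex14 = 0, Hex15 = 0, Hex16 = 0, Hex17 = 0, Hex18 = 0
  )
  w / sum(w)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, " proteins:", object@nProteins,
      " length:", paste(object@lengthRange, collapse = "-"), "\n")
  cat("  sequon density:", object@sequonDensity, "/100 res;",
      "occupancy:", object@occupancy, "; coverage:", object@coverage, "\n")
  cat("  conditions:", object@nConditions,
      "; dispersion:", object@abundanceDispersion, "\n")
  cat("  homolog retention:", object@homologRetention,
      "; indel rate:", object@indelRate, "\n")
  cat("  glycan pool: Hex", paste(range(which(object@glycanWeights > 0) + 2),
      collapse = ".."), "; mass error sd:", object@massErrorSd, "Da\n")
})

#' Secretome container
#'
#' A set of (simulated or parsed) secreted proteins: the amino-acid sequences
#' as an \code{AAStringSet}, a per-protein annotation table (CAZy family,
#' secretion flag, functional group) and, for simulated data, the
#' ground-truth site table.
#'
#' @slot sequences \code{AAStringSet} of protein sequences.
#' @slot annotations \code{DataFrame} with one row per protein: columns
#'   \code{protein_id}, \code{cazy_family} (";"-joined labels or "non-CAZy"),
#'   \code{secreted}, \code{group}.
#' @slot truth \code{DataFrame} of planted sites (\code{protein_id},
#'   \code{position}, \code{occupied}); zero rows for non-simulated data.
#'
#' @export
setClass("Secretome", representation(
  sequences = "AAStringSet",
  annotations = "DataFrame",
  truth = "DataFrame"
))

setValidity("Secretome", function(object) {
  msg <- character()
  if (length(object@sequences) != nrow(object@annotations)) {
    msg <- c(msg, "one annotation row per sequence required")
  }
  if (!all(c("protein_id", "cazy_family", "secreted") %in%
             colnames(object@annotations))) {
    msg <- c(msg, "annotations need protein_id, cazy_family, secreted")
  }
  if (length(object@sequences) &&
      !identical(object@annotations$protein_id, names(object@sequences))) {
    msg <- c(msg, "annotation rows must align with sequence names")
  }
  if (nrow(object@truth)) {
    if (!all(object@truth$protein_id %in% names(object@sequences))) {
      msg <- c(msg, "truth refers to unknown proteins")
    } else {
      seqs <- as.character(object@sequences)[object@truth$protein_id]
      asn <- substr(seqs, object@truth$position, object@truth$position)
      if (!all(asn == "N")) {
        msg <- c(msg, "every truth label must point at an Asn in the FASTA")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Secretome-class number of proteins.
#' @param x,object a \code{Secretome}.
#' @export
setMethod("length", "Secretome", function(x) length(x@sequences))

#' Accessors for Secretome and HomologAlignment
#'
#' \code{proteins()} returns the \code{AAStringSet}; \code{annotations()} the
#' per-protein annotation table; \code{groundTruth()} the planted-site truth
#' table (simulated data only).
#'
#' @param x a \linkS4class{Secretome}.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setMethod("proteins", "Secretome", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "Secretome", function(x) x@annotations)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "Secretome", function(x) x@truth)

setMethod("show", "Secretome", function(object) {
  cat("Secretome with", length(object), "proteins\n")
  if (length(object)) {
    w <- Biostrings::width(object@sequences)
    cat("  lengths:", min(w), "-", max(w), "residues\n")
    caz <- sum(object@annotations$cazy_family != "non-CAZy")
    cat("  CAZy-annotated:", caz, "; secreted:",
        sum(object@annotations$secreted), "\n")
  }
  if (nrow(object@truth)) {
    cat("  ground truth:", nrow(object@truth), "planted sites (",
        sum(object@truth$occupied), "occupied )\n")
  }
})

#' Homolog multiple alignment
#'
#' An aligned homolog family: equal-width gapped sequences with the query
#' flagged by id. The degapped query must equal the original protein
#' sequence. The BLAST E-value gate that defined family membership (e.g.
#' E <= 1e-70) is upstream of this package and recorded as metadata only.
#'
#' @slot alignment \code{AAStringSet} of gapped rows ('-' gap character).
#' @slot queryId id of the query row.
#'
#' @export
setClass("HomologAlignment", representation(
  alignment = "AAStringSet",
  queryId = "character"
))

setValidity("HomologAlignment", function(object) {
  msg <- character()
  if (length(object@alignment) < 1L) {
    msg <- c(msg, "alignment must contain at least the query row")
  } else {
    if (length(unique(Biostrings::width(object@alignment))) != 1L) {
      msg <- c(msg, "all alignment rows must have equal width")
    }
    if (!object@queryId %in% names(object@alignment)) {
      msg <- c(msg, "queryId must name a row of the alignment")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HomologAlignment
#'
#' @param alignment named \code{AAStringSet} (or named character vector) of
#'   equal-width gapped rows.
#' @param queryId id of the query row; defaults to the first row.
#' @return A \linkS4class{HomologAlignment}.
#' @export
homologAlignment <- function(alignment, queryId = NULL) {
  if (is.character(alignment)) {
    alignment <- Biostrings::AAStringSet(alignment)
  }
  if (is.null(queryId)) queryId <- names(alignment)[1]
  new("HomologAlignment", alignment = alignment, queryId = queryId)
}

#' @describeIn HomologAlignment-class number of rows (query included).
#' @param x,object a \code{HomologAlignment}.
#' @export
setMethod("length", "HomologAlignment", function(x) length(x@alignment))

#' @rdname accessors
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))
#' @rdname accessors
#' @export
setMethod("queryId", "HomologAlignment", function(x) x@queryId)

#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @rdname accessors
#' @export
setMethod("alignmentRows", "HomologAlignment", function(x) x@alignment)

#' Degapped query sequence of an alignment
#'
#' @param x a \linkS4class{HomologAlignment}.
#' @return Character scalar: the query row with gaps removed.
#' @export
setGeneric("querySequence", function(x) standardGeneric("querySequence"))
#' @rdname querySequence
#' @export
setMethod("querySequence", "HomologAlignment", function(x) {
  gsub("-", "", as.character(x@alignment[[x@queryId]]), fixed = TRUE)
})

setMethod("show", "HomologAlignment", function(object) {
  cat("HomologAlignment: ", length(object) - 1L, " homologs + query '",
      object@queryId, "', ", Biostrings::width(object@alignment)[1],
      " columns\n", sep = "")
})
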