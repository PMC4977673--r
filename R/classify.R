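## Three-class evidence classification of predicted sequons:
##   validated     - covered and carrying >= minTagged GlcNAc-remnant
##                   observations at the site Asn
##   non_validated - covered by peptides but never tagged at that Asn
##   non_covered   - no identified peptide spans the Asn
## The classes are disjoint and exhaustive over predicted sites.

#' Classify predicted sites by peptide evidence
#'
#' Partitions sequon sites into the three evidence classes. A site is
#' \emph{validated} when at least \code{minTagged} tagged observations place
#' a GlcNAc remnant (+203 Da) on the site's Asn; \emph{non_validated} when
#' covered but never tagged there (non-glycosylated on this evidence);
#' \emph{non_covered} when no observed peptide spans the Asn.
#'
#' Evidence rows claiming a GlcNAc remnant on a residue that is not a sequon
#' Asn are inconsistent: they are reported via \code{warning()} and the
#' offending modification is ignored for classification.
#'
#' @param sites site table from \code{\link{scanSequons}}.
#' @param evidence peptide-evidence data.frame (dialect of
#'   \code{\link{readEvidence}}).
#' @param minTagged minimum number of tagged observations required for
#'   "validated" (default 1: presence-based, the study definition). Raising
#'   it emulates a stricter re-validation of the tagged set.
#' @param countSpectra if \code{TRUE} tagged observations are weighted by
#'   \code{spectrum_count}; default \code{FALSE} counts evidence rows.
#' @return \code{sites} with \code{status} set and columns \code{covered},
#'   \code{n_tagged_spectra} added.
#' @examples
#' sites <- scanSequons(c(p = "AAKNATAAK"))
#' ev <- data.frame(protein_id = "p", peptide = "NATAAK", start = 4, end = 9,
#'                  mods = "GlcNAc_remnant@1", spectrum_count = 3,
#'                  condition = "glucose")
#' classifySites(sites, ev)
#' @export
classifySites <- function(sites, evidence, minTagged = 1L,
                          countSpectra = FALSE) {
  sites <- mapCoverage(evidence, sites)
  sites$n_tagged_spectra <- 0L
  sites$status <- ifelse(sites$covered, "non_validated", "non_covered")
  if (nrow(evidence)) {
    sequonKey <- paste(sites$protein_id, sites$position)
    for (i in seq_len(nrow(evidence))) {
      mods <- parseModString(evidence$mods[i])
      mods <- mods[mods$name == "GlcNAc_remnant", , drop = FALSE]
      if (!nrow(mods)) next
      absPos <- evidence$start[i] + mods$position - 1L
      keys <- paste(evidence$protein_id[i], absPos)
      known <- keys %in% sequonKey
      if (any(!known)) {
        warning(
          "GlcNAc remnant on a non-sequon residue (", evidence$protein_id[i],
          " position ", paste(absPos[!known], collapse = ","),
          "); ignored as inconsistent evidence"
        )
      }
      if (any(known)) {
        idx <- match(keys[known], sequonKey)
        wt <- if (countSpectra) evidence$spectrum_count[i] else 1L
        sites$n_tagged_spectra[idx] <- sites$n_tagged_spectra[idx] + wt
      }
    }
  }
  sites$status[sites$covered & sites$n_tagged_spectra >= minTagged] <-
    "validated"
  sites
}

#' Summarise classified sites
#'
#' Global status counts plus per-protein validated-site listings in the
#' "N<pos>" convention (positions joined as e.g. "225, 365"), and
#' CAZy-restricted tallies.
#'
#' @param sites classified site table from \code{\link{classifySites}}.
#' @param annotations per-protein annotation table (columns
#'   \code{protein_id}, \code{cazy_family}); \code{NULL} treats all proteins
#'   as unannotated.
#' @return List with elements \code{status_counts} (named integer vector
#'   over validated/non_validated/non_covered), \code{n_sites},
#'   \code{validated_in_cazy} (validated sites on CAZy-annotated proteins),
#'   \code{n_cazy_proteins_validated} (distinct CAZy proteins with >= 1
#'   validated site) and \code{per_protein} (data.frame: protein_id,
#'   n_validated, validated_positions).
#' @export
summarizeSites <- function(sites, annotations = NULL) {
  statuses <- setdiff(.SITE_STATUSES, "unset")
  counts <- setNames(integer(length(statuses)), statuses)
  tab <- table(factor(sites$status, levels = statuses))
  counts[names(tab)] <- as.integer(tab)
  val <- sites[sites$status == "validated", , drop = FALSE]
  per <- if (nrow(val)) {
    sp <- split(val$position, val$protein_id)
    data.frame(
      protein_id = names(sp),
      n_validated = lengths(sp),
      validated_positions = vapply(
        sp, function(p) paste(sort(p), collapse = ", "), character(1)
      ),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(protein_id = character(), n_validated = integer(),
               validated_positions = character(), stringsAsFactors = FALSE)
  }
  cazIds <- character()
  if (!is.null(annotations)) {
    cazIds <- annotations$protein_id[annotations$cazy_family != "non-CAZy"]
  }
  list(
    status_counts = counts,
    n_sites = nrow(sites),
    validated_in_cazy = sum(val$protein_id %in% cazIds),
    n_cazy_proteins_validated = length(
      intersect(unique(val$protein_id), cazIds)
    ),
    per_protein = per
  )
}
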