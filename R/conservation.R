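## Conservation of glycosylation sites across homolog alignments: map the
## query's site Asn to its alignment column, ask whether each homolog
## retains an intact sequon at (or near) that column, and report per-site
## conservation percentages.

#' Map a query site position to its alignment column
#'
#' Alignment columns are 1-based; for a gapless query, column == position.
#' Gap columns in the query shift sites rightwards.
#'
#' @param msa a \linkS4class{HomologAlignment}.
#' @param position 1-based position(s) in the degapped query.
#' @return Integer vector of 1-based alignment columns.
#' @export
mapSiteToColumn <- function(msa, position) {
  qrow <- as.character(alignmentRows(msa)[[queryId(msa)]])
  chars <- strsplit(qrow, "")[[1]]
  residueCols <- which(chars != "-")
  position <- as.integer(position)
  if (any(position < 1L | position > length(residueCols))) {
    stop("site position outside the degapped query")
  }
  residueCols[position]
}

#' Is a site conserved in one homolog row?
#'
#' A site is conserved in a homolog when the homolog carries an Asn within
#' \code{windowTol} columns of the mapped query column whose degapped
#' context is an intact N-X-S/T sequon (X != P unless
#' \code{allowProlineX}). \code{windowTol = 0} demands strict column
#' identity; positive tolerances accept sequons shifted by alignment gaps,
#' which the study observed to sit at similar positions in 3-D despite
#' primary-sequence shifts.
#'
#' @param row gapped homolog sequence (character scalar).
#' @param column 1-based alignment column of the query site Asn.
#' @param windowTol column tolerance (default 0).
#' @param allowProlineX passed to the sequon rule.
#' @return List: \code{conserved} (logical) and \code{offset} (signed column
#'   displacement of the matched Asn, NA when not conserved).
#' @export
siteConservedIn <- function(row, column, windowTol = 0L,
                            allowProlineX = FALSE) {
  chars <- strsplit(as.character(row), "")[[1]]
  if (column < 1L || column > length(chars)) stop("column outside alignment")
  degapIdx <- cumsum(chars != "-")     # degapped position of each column
  degapped <- paste(chars[chars != "-"], collapse = "")
  cand <- seq(max(1L, column - windowTol),
              min(length(chars), column + windowTol))
  cand <- cand[order(abs(cand - column), cand)]   # nearest first
  for (cc in cand) {
    if (chars[cc] != "N") next
    pos <- degapIdx[cc]
    if (pos + 2L > nchar(degapped)) next
    xres <- substr(degapped, pos + 1L, pos + 1L)
    tres <- substr(degapped, pos + 2L, pos + 2L)
    if (!tres %in% c("S", "T")) next
    if (!allowProlineX && xres == "P") next
    return(list(conserved = TRUE, offset = cc - column))
  }
  list(conserved = FALSE, offset = NA_integer_)
}

#' Per-site conservation percentages over a homolog family
#'
#' For each query site, the percentage of non-query rows that retain an
#' intact sequon at the mapped column (within \code{windowTol} columns).
#' Percentages are rendered to one decimal.
#'
#' @param msa a \linkS4class{HomologAlignment}.
#' @param sites site table for the query protein (needs \code{position};
#'   typically the validated subset from \code{\link{classifySites}}).
#' @param windowTol column tolerance passed to
#'   \code{\link{siteConservedIn}}.
#' @param allowProlineX passed to the sequon rule.
#' @return data.frame: \code{position}, \code{column}, \code{n_homologs},
#'   \code{n_conserved}, \code{conservation_pct}, plus a list-column
#'   \code{offsets} of per-homolog displacements (NA = not conserved).
#' @examples
#' aln <- homologAlignment(c(q = "AANATAA", h1 = "AANATAA", h2 = "AADATAA"))
#' conservationPercent(aln, data.frame(position = 3))
#' @export
conservationPercent <- function(msa, sites, windowTol = 0L,
                                allowProlineX = FALSE) {
  rows <- alignmentRows(msa)
  others <- rows[setdiff(names(rows), queryId(msa))]
  cols <- mapSiteToColumn(msa, sites$position)
  res <- lapply(seq_along(cols), function(i) {
    verdicts <- lapply(as.character(others), siteConservedIn,
                       column = cols[i], windowTol = windowTol,
                       allowProlineX = allowProlineX)
    nC <- sum(vapply(verdicts, `[[`, logical(1), "conserved"))
    list(
      n_conserved = nC,
      offsets = vapply(verdicts, `[[`, integer(1), "offset")
    )
  })
  out <- data.frame(
    position = sites$position,
    column = cols,
    n_homologs = length(others),
    n_conserved = vapply(res, `[[`, integer(1), "n_conserved"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$conservation_pct <- round(
    100 * out$n_conserved / pmax(out$n_homologs, 1L), 1
  )
  out$offsets <- lapply(res, `[[`, "offsets")
  out
}

#' Read an aligned FASTA as a HomologAlignment
#'
#' The first record is taken as the query unless \code{queryId} names
#' another row.
#'
#' @param path aligned FASTA file.
#' @param queryId optional id of the query row.
#' @return A \linkS4class{HomologAlignment}.
#' @export
readHomologAlignment <- function(path, queryId = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  homologAlignment(aln, queryId = queryId)
}
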