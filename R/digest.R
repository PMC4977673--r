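## In-silico tryptic digestion and monoisotopic peptide mass arithmetic.
## Trypsin cleaves C-terminal of K/R except before proline; the study's
## search allowed one missed cleavage.

#' Tryptic digest of a protein
#'
#' Cleaves after K or R except when the next residue is proline, and emits
#' all peptides with 0..\code{maxMissed} missed cleavages within the length
#' bounds. Zero-missed peptides tile the protein exactly.
#'
#' @param sequence protein sequence (character scalar) or a named length-1
#'   vector; the name is used as \code{protein_id}.
#' @param maxMissed maximum missed cleavages (default 1, the study setting).
#' @param minLength,maxLength peptide length bounds; \code{NULL} = unbounded.
#' @param proteinId id recorded in the output (defaults to the sequence
#'   name, else "protein").
#' @return data.frame: \code{protein_id}, \code{start}, \code{end} (1-based
#'   inclusive), \code{sequence}, \code{missed_cleavages}.
#' @examples
#' digestProtein("AAKGGR", maxMissed = 1)
#' @export
digestProtein <- function(sequence, maxMissed = 1L, minLength = 1L,
                          maxLength = NULL, proteinId = NULL) {
  if (is.null(proteinId)) {
    proteinId <- if (!is.null(names(sequence))) names(sequence)[1] else
      "protein"
  }
  s <- unname(sequence[1])
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  # cleavage sites: after position i when chars[i] in K/R and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)                # fragment boundaries
  starts0 <- bounds[-length(bounds)] + 1L      # zero-missed fragment starts
  ends0 <- bounds[-1]
  k <- length(starts0)
  res <- list()
  for (mc in 0:maxMissed) {
    if (k - mc < 1L) break
    i <- seq_len(k - mc)
    res[[mc + 1L]] <- data.frame(
      protein_id = proteinId,
      start = starts0[i],
      end = ends0[i + mc],
      missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$sequence <- substr(rep(s, nrow(out)), out$start, out$end)
  len <- out$end - out$start + 1L
  keep <- len >= minLength
  if (!is.null(maxLength)) keep <- keep & len <= maxLength
  out <- out[keep, c("protein_id", "start", "end", "sequence",
                     "missed_cleavages")]
  rownames(out) <- NULL
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus water plus modification deltas.
#' Understood modifications (see \code{\link{modificationMasses}}):
#' \code{GlcNAc_remnant} (+203.0794, Asn only), \code{carbamidomethyl}
#' (+57.0215, Cys only), \code{oxidation} (+15.9949, Met only).
#'
#' @param sequence peptide sequence (character scalar).
#' @param mods optional data.frame with columns \code{name} and
#'   \code{position} (1-based within the peptide), or a character vector in
#'   the evidence dialect "name@position" (e.g. "GlcNAc_remnant@3").
#' @return Monoisotopic mass in Da.
#' @examples
#' peptideMass("PEPTIDE")  # 799.3600
#' @export
peptideMass <- function(sequence, mods = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% .AMINO_ACIDS)) {
    stop("non-standard residue in peptide '", sequence, "'")
  }
  m <- sum(.RESIDUE_MASS[chars]) + .MASS_WATER
  if (!is.null(mods) && length(mods)) {
    if (is.character(mods)) mods <- parseModString(mods)
    bad <- !mods$name %in% .MODIFICATIONS$name
    if (any(bad)) stop("unknown modification: ", mods$name[bad][1])
    target <- .MODIFICATIONS$target[match(mods$name, .MODIFICATIONS$name)]
    if (any(mods$position < 1L | mods$position > length(chars))) {
      stop("modification position outside peptide")
    }
    if (any(chars[mods$position] != target)) {
      i <- which(chars[mods$position] != target)[1]
      stop(
        "modification ", mods$name[i], " on incompatible residue ",
        chars[mods$position[i]], " at position ", mods$position[i]
      )
    }
    m <- m + sum(.MODIFICATIONS$delta[match(mods$name, .MODIFICATIONS$name)])
  }
  unname(m)
}

#' Parse the semicolon-joined modification dialect
#'
#' Evidence tables encode modifications as "name@position" joined by ";",
#' e.g. \code{"carbamidomethyl@2;GlcNAc_remnant@5"}. Empty strings and "-"
#' mean no modifications.
#'
#' @param x character vector of modification strings.
#' @return data.frame with \code{name} and \code{position} columns (all rows
#'   concatenated when \code{x} has length > 1).
#' @export
parseModString <- function(x) {
  x <- x[!is.na(x) & nzchar(x) & x != "-"]
  if (!length(x)) {
    return(data.frame(name = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- unlist(strsplit(x, ";", fixed = TRUE))
  parts <- parts[nzchar(parts)]
  hit <- regmatches(parts, regexec("^([A-Za-z_]+)@([0-9]+)$", parts))
  if (any(lengths(hit) != 3L)) {
    stop("malformed modification token: '",
         parts[which(lengths(hit) != 3L)[1]], "'")
  }
  data.frame(
    name = vapply(hit, `[`, character(1), 2),
    position = as.integer(vapply(hit, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

#' Map peptide evidence onto predicted sites
#'
#' A site is covered iff some observed peptide's [start..end] interval on
#' the same protein contains the site's Asn position.
#'
#' @param evidence peptide-evidence data.frame (see
#'   \code{\link{readEvidence}} for the dialect): needs \code{protein_id},
#'   \code{start}, \code{end}; row identity is taken from rownames.
#' @param sites site table from \code{\link{scanSequons}}.
#' @param proteinIds optional character vector of known protein ids; when
#'   supplied, evidence referencing other proteins is an error.
#' @return \code{sites} with two added columns: \code{covered} (logical) and
#'   \code{peptide_rows} (comma-joined evidence row indices covering the
#'   site, "" when uncovered).
#' @export
mapCoverage <- function(evidence, sites, proteinIds = NULL) {
  if (!is.null(proteinIds)) {
    unknown <- setdiff(unique(evidence$protein_id), proteinIds)
    if (length(unknown)) {
      stop("evidence references unknown proteins: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  sites$covered <- FALSE
  sites$peptide_rows <- ""
  if (!nrow(sites) || !nrow(evidence)) return(sites)
  # interval overlap per protein via IRanges
  for (pid in unique(sites$protein_id)) {
    si <- which(sites$protein_id == pid)
    ei <- which(evidence$protein_id == pid)
    if (!length(ei)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$position[si], width = 1L),
      IRanges::IRanges(evidence$start[ei], evidence$end[ei])
    )
    if (!length(hits)) next
    cov <- split(ei[S4Vectors::subjectHits(hits)],
                 si[S4Vectors::queryHits(hits)])
    idx <- as.integer(names(cov))
    sites$covered[idx] <- TRUE
    sites$peptide_rows[idx] <- vapply(cov, paste, character(1),
                                      collapse = ",")
  }
  sites
}
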