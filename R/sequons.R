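## Rule-based sequon scanning. The eukaryotic acceptor motif is
## Asn-X-Ser/Thr; by default X may not be proline, matching OST specificity.
## Coordinates are 1-based throughout the package.

#' Scan protein sequences for N-glycosylation sequons
#'
#' Finds every N-X-S/T acceptor sequon in a protein set. By default X is any
#' residue except proline (the oligosaccharyltransferase does not glycosylate
#' N-P-S/T); set \code{allowProlineX = TRUE} for the literal N-X-S/T reading.
#' Overlapping sequons are all reported. Sequons truncated by the C terminus
#' (no +2 residue) are not sequons.
#'
#' @param x a \linkS4class{Secretome}, \code{AAStringSet}, or named character
#'   vector of protein sequences.
#' @param allowProlineX logical; if \code{TRUE}, X may be proline.
#' @param halfWidth flanking half-width for the reported window (default 6,
#'   i.e. positions -6..+6).
#' @return A data.frame of sites, one row per sequon, in ascending position
#'   per protein: \code{protein_id}, \code{position} (1-based Asn index),
#'   \code{sequon} (3-residue string), \code{sequon_type} ("NXS"/"NXT"),
#'   \code{window} (13-character flank, '-'-padded, center rendered 'n'),
#'   \code{status} (initialised to "unset").
#' @examples
#' scanSequons(c(p1 = "MNASNTTAPK"))
#' @export
scanSequons <- function(x, allowProlineX = FALSE, halfWidth = 6L) {
  seqs <- .asSequenceVector(x)
  pat <- if (allowProlineX) "N(?=.[ST])" else "N(?=[^P][ST])"
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- as.integer(m)
    data.frame(
      protein_id = id,
      position = pos,
      sequon = substr(rep(s, length(pos)), pos, pos + 2L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(
      protein_id = character(), position = integer(), sequon = character(),
      sequon_type = character(), window = character(), status = character(),
      stringsAsFactors = FALSE
    ))
  }
  out$sequon_type <- ifelse(substr(out$sequon, 3, 3) == "T", "NXT", "NXS")
  out$window <- flankingWindow(seqs[out$protein_id], out$position,
                               halfWidth = halfWidth)
  out$status <- "unset"
  rownames(out) <- NULL
  out
}

#' Extract the flanking window around an Asn site
#'
#' Returns the \code{2*halfWidth + 1}-character window centred on a site
#' asparagine, rendered lower-case 'n' at the centre and padded with '-'
#' where the protein terminates inside the window.
#'
#' @param x protein sequence(s): character vector, \code{AAStringSet} or
#'   \linkS4class{Secretome}. Recycled against \code{position}.
#' @param position 1-based index of the site Asn.
#' @param halfWidth number of residues on each side (default 6).
#' @return Character vector of windows.
#' @examples
#' flankingWindow("NATAAAAAAAAA", 1)  # "------nATAAAA"
#' @export
flankingWindow <- function(x, position, halfWidth = 6L) {
  seqs <- unname(.asSequenceVector(x))
  n <- max(length(seqs), length(position))
  seqs <- rep_len(seqs, n)
  position <- rep_len(as.integer(position), n)
  len <- nchar(seqs)
  if (any(position < 1L | position > len)) {
    stop("position out of range for its protein")
  }
  if (any(substr(seqs, position, position) != "N")) {
    stop("flanking windows are defined around Asn residues only")
  }
  vapply(seq_len(n), function(i) {
    lo <- position[i] - halfWidth
    hi <- position[i] + halfWidth
    chars <- strsplit(substr(seqs[i], max(lo, 1L), min(hi, len[i])), "")[[1]]
    pad_l <- max(0L, 1L - lo)
    pad_r <- max(0L, hi - len[i])
    w <- c(rep("-", pad_l), chars, rep("-", pad_r))
    w[halfWidth + 1L] <- "n"
    paste(w, collapse = "")
  }, character(1))
}

# Coerce supported inputs to a named character vector of validated sequences.
.asSequenceVector <- function(x) {
  if (is(x, "Secretome")) x <- proteins(x)
  if (is(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("cannot interpret input as protein sequences")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  if (any(!nzchar(x))) stop("empty protein sequence")
  bad <- grepl(paste0("[^", paste(.AMINO_ACIDS, collapse = ""), "]"), x)
  if (any(bad)) {
    stop(
      "non-standard residues in: ",
      paste(utils::head(names(x)[bad], 5), collapse = ", ")
    )
  }
  x
}
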