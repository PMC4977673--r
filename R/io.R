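## Plain-text IO. All tables are TSV with '#'-prefixed header lines
## carrying the file conventions (1-based coordinates, monoisotopic masses,
## sodiated adduct). The evidence parser is strict: malformed rows are
## reported with their line numbers.

.EVIDENCE_COLS <- c("protein_id", "peptide", "start", "end", "mods",
                    "spectrum_count", "condition")

#' Write a table as commented TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @param comments character vector of convention notes written as
#'   '#'-prefixed header lines.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV
#'
#' @param path file written by \code{\link{writeTsv}} (or any TSV whose
#'   comment lines start with '#').
#' @return data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a peptide-evidence table
#'
#' Strict parser for the evidence dialect: tab-separated columns
#' \code{protein_id}, \code{peptide}, \code{start}, \code{end}, \code{mods}
#' (";"-joined "name@position", "" or "-" for none), \code{spectrum_count},
#' \code{condition}. Violations (missing columns, non-integer coordinates,
#' peptide/coordinate mismatches against \code{proteins} when supplied,
#' malformed modification tokens) are reported with the offending record.
#'
#' @param path TSV file.
#' @param proteins optional protein set for coordinate validation.
#' @return Evidence data.frame.
#' @export
readEvidence <- function(path, proteins = NULL) {
  ev <- readTsv(path)
  missing <- setdiff(.EVIDENCE_COLS, colnames(ev))
  if (length(missing)) {
    stop("evidence file ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  ev <- ev[.EVIDENCE_COLS]
  ev$mods[is.na(ev$mods)] <- ""
  if (!is.numeric(ev$start) || !is.numeric(ev$end) ||
      any(ev$start != as.integer(ev$start)) ||
      any(ev$end != as.integer(ev$end))) {
    stop("evidence file ", path, ": start/end must be integers")
  }
  bad <- which(ev$start < 1L | ev$end < ev$start)
  if (length(bad)) {
    stop("evidence file ", path, ": invalid coordinates at record ",
         bad[1])
  }
  parseModString(ev$mods)   # validates tokens, errors on malformed
  if (!is.null(proteins)) {
    seqs <- .asSequenceVector(proteins)
    unknown <- which(!ev$protein_id %in% names(seqs))
    if (length(unknown)) {
      stop("evidence file ", path, ": unknown protein '",
           ev$protein_id[unknown[1]], "' at record ", unknown[1])
    }
    slice <- substr(seqs[ev$protein_id], ev$start, ev$end)
    mism <- which(slice != ev$peptide)
    if (length(mism)) {
      stop("evidence file ", path,
           ": peptide/coordinate mismatch at record ", mism[1])
    }
  }
  ev
}

#' Write a Secretome to FASTA + annotation TSV
#'
#' @param secretome a \linkS4class{Secretome}.
#' @param fastaPath,annotationPath,truthPath output files;
#'   \code{truthPath = NULL} skips the ground-truth table.
#' @param seed seed recorded in the output headers.
#' @return Invisible character vector of the written paths.
#' @export
writeSecretome <- function(secretome, fastaPath, annotationPath,
                           truthPath = NULL, seed = NA) {
  Biostrings::writeXStringSet(proteins(secretome), fastaPath)
  note <- paste("simulation seed:", seed)
  writeTsv(as.data.frame(annotations(secretome)), annotationPath,
           comments = c("per-protein annotations", note))
  paths <- c(fastaPath, annotationPath)
  if (!is.null(truthPath)) {
    writeTsv(as.data.frame(groundTruth(secretome)), truthPath,
             comments = c("ground truth; 1-based Asn positions", note))
    paths <- c(paths, truthPath)
  }
  invisible(paths)
}

#' Read a Secretome from FASTA + annotation TSV
#'
#' @param fastaPath protein FASTA.
#' @param annotationPath annotation TSV (\code{protein_id},
#'   \code{cazy_family}, \code{secreted}, optional \code{group}); missing
#'   file annotates everything as non-CAZy secreted.
#' @param truthPath optional ground-truth TSV.
#' @return A \linkS4class{Secretome}.
#' @export
readSecretome <- function(fastaPath, annotationPath = NULL,
                          truthPath = NULL) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(annotationPath)) {
    ann <- readTsv(annotationPath)
    ann <- ann[match(names(seqs), ann$protein_id), ]
    if (anyNA(ann$protein_id)) {
      stop("annotation table does not cover all FASTA records")
    }
    if (is.null(ann$group)) ann$group <- "other"
    ann <- DataFrame(ann)
  } else {
    ann <- DataFrame(
      protein_id = names(seqs),
      cazy_family = "non-CAZy",
      secreted = TRUE,
      group = "other"
    )
  }
  truth <- if (!is.null(truthPath)) DataFrame(readTsv(truthPath)) else
    DataFrame(
      protein_id = character(), position = integer(),
      sequon_type = character(), occupied = logical()
    )
  new("Secretome", sequences = seqs, annotations = ann, truth = truth)
}
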