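## Flanking-sequence motif statistics for validated sites: the motif report
## (dataset vs background percentages), NXT/NXS preference per evidence
## class, and the chemical-class profile of flanking residues.

#' Motif report over flanking windows
#'
#' Counts window matches for each motif pattern and computes dataset and
#' background percentages. A motif is a 13-character pattern over residue
#' letters, '.' (any residue) and a single 'n' marking the site Asn, e.g.
#' \code{"......n.T...."} for N-X-T. Terminal '-' pad characters never match
#' a residue letter or '.'.
#'
#' The background percentage is computed over all Asn-centred windows in the
#' background protein set: for each Asn in each background protein a window
#' is cut and matched the same way, so for \code{"......n.T...."} the
#' background percentage approximates the Thr residue frequency.
#'
#' @param windows character vector of 13-character site windows (centre 'n').
#' @param motifs character vector of motif patterns.
#' @param background optional background proteins (\linkS4class{Secretome},
#'   \code{AAStringSet} or named character); \code{NULL} leaves background
#'   columns \code{NA}.
#' @param binomialP if \code{TRUE}, adds a one-sided binomial enrichment
#'   p-value per motif (dataset matches vs background probability).
#' @return data.frame: \code{motif}, \code{dataset_matches},
#'   \code{dataset_pct} (1-decimal display rounding of
#'   100*matches/n_windows), \code{background_pct}, \code{fold_enrichment},
#'   optionally \code{binomial_p}. The unrounded fraction is kept in
#'   \code{dataset_pct_exact}.
#' @examples
#' w <- motifPreset("nidulans151")
#' motifReport(w, c("......n.T....", "......n.S...."))
#' @export
motifReport <- function(windows, motifs, background = NULL,
                        binomialP = FALSE) {
  if (!length(windows)) stop("empty window set")
  .checkWindows(windows)
  vapply(motifs, .checkMotif, logical(1))
  n <- length(windows)
  matches <- vapply(
    motifs, function(m) sum(.matchMotif(windows, m)), integer(1)
  )
  pct_exact <- 100 * matches / n
  bg_pct <- rep(NA_real_, length(motifs))
  if (!is.null(background)) {
    bw <- backgroundWindows(background)
    if (length(bw)) {
      bg_pct <- vapply(
        motifs, function(m) 100 * mean(.matchMotif(bw, m)), numeric(1)
      )
    }
  }
  out <- data.frame(
    motif = motifs,
    dataset_matches = matches,
    dataset_pct = round(pct_exact, 1),
    dataset_pct_exact = pct_exact,
    background_pct = round(bg_pct, 2),
    fold_enrichment = ifelse(
      !is.na(bg_pct) & bg_pct > 0, pct_exact / bg_pct, NA_real_
    ),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (binomialP) {
    out$binomial_p <- ifelse(
      is.na(bg_pct), NA_real_,
      mapply(function(k, p) {
        stats::pbinom(k - 1L, n, max(min(p / 100, 1), 0),
                      lower.tail = FALSE)
      }, matches, bg_pct)
    )
  }
  attr(out, "n_windows") <- n
  out
}

#' All Asn-centred windows of a background protein set
#'
#' @param background \linkS4class{Secretome}, \code{AAStringSet} or named
#'   character vector.
#' @param halfWidth window half-width (default 6).
#' @return Character vector of windows (one per Asn occurrence).
#' @export
backgroundWindows <- function(background, halfWidth = 6L) {
  seqs <- .asSequenceVector(background)
  unlist(lapply(names(seqs), function(id) {
    m <- gregexpr("N", seqs[[id]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(character())
    flankingWindow(seqs[id], as.integer(m), halfWidth = halfWidth)
  }), use.names = FALSE)
}

#' Sequon-type preference per evidence class
#'
#' Percentage of NXT vs NXS sequons within each site status. In the
#' secretome this study emulates, N-X-T dominated validated sites (72.2 vs
#' 27.8) while N-X-S dominated the non-validated class.
#'
#' @param sites classified site table (columns \code{sequon_type},
#'   \code{status}).
#' @return data.frame: \code{status}, \code{n}, \code{pct_NXT},
#'   \code{pct_NXS} (percentages sum to 100 per status).
#' @export
sequonPreference <- function(sites) {
  sp <- split(sites$sequon_type, sites$status)
  out <- data.frame(
    status = names(sp),
    n = lengths(sp),
    pct_NXT = vapply(sp, function(x) 100 * mean(x == "NXT"), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$pct_NXS <- 100 - out$pct_NXT
  out
}

#' Chemical-class profile of flanking residues
#'
#' Frequency of each side-chain chemical class at window positions -6..+6,
#' excluding position 0 (the Asn) and +2 (the sequon Ser/Thr), which are
#' fixed by the sequon and not informative. Pad characters ('-') are
#' excluded from denominators, so each position's class frequencies sum to 1
#' over observed residues.
#'
#' @param windows character vector of 13-character windows.
#' @return data.frame with columns \code{position} (-6..+6 without 0, +2),
#'   one column per class (see \code{\link{chemicalClasses}}), and
#'   \code{n_residues} (non-pad count at that position).
#' @export
flankingClassProfile <- function(windows) {
  .checkWindows(windows)
  positions <- setdiff(-6:6, c(0L, 2L))
  classes <- chemicalClasses()
  rows <- lapply(positions, function(p) {
    ch <- substr(windows, p + 7L, p + 7L)
    ch <- ch[ch != "-"]
    freq <- vapply(classes, function(cl) mean(ch %in% cl), numeric(1))
    if (!length(ch)) freq[] <- NA_real_
    c(list(position = p), as.list(freq), list(n_residues = length(ch)))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Greedy motif search over site windows
#'
#' A simple motif-x-style search: starting from the bare sequon pattern,
#' repeatedly fixes the (position, residue) pair with the smallest binomial
#' enrichment p-value against the background until no addition is
#' significant, then removes the matching windows and restarts. Provided for
#' exploration; the motif report itself is input-driven.
#'
#' @param windows site windows (13 characters).
#' @param background background protein set for residue probabilities.
#' @param alpha significance threshold per addition (default 1e-4).
#' @param minMatches minimum windows a motif must match (default 10).
#' @param maxMotifs maximum motifs returned.
#' @return Character vector of motif patterns.
#' @export
motifSearch <- function(windows, background, alpha = 1e-4,
                        minMatches = 10L, maxMotifs = 10L) {
  .checkWindows(windows)
  bw <- backgroundWindows(background)
  found <- character()
  pool <- windows
  for (k in seq_len(maxMotifs)) {
    if (length(pool) < minMatches) break
    pattern <- strsplit("......n......", "")[[1]]
    active <- pool
    bact <- bw
    repeat {
      open <- setdiff(which(pattern == "."), 7L)
      best <- NULL
      for (p in open) {
        ch <- substr(active, p, p)
        bch <- substr(bact, p, p)
        for (r in unique(ch[ch != "-"])) {
          k_obs <- sum(ch == r)
          if (k_obs < minMatches) next
          pr <- max(mean(bch == r), 1e-9)
          pv <- stats::pbinom(k_obs - 1L, length(active), pr,
                              lower.tail = FALSE)
          if (is.null(best) || pv < best$pv) {
            best <- list(pos = p, res = r, pv = pv)
          }
        }
      }
      if (is.null(best) || best$pv > alpha) break
      pattern[best$pos] <- best$res
      keep <- substr(active, best$pos, best$pos) == best$res
      active <- active[keep]
      bact <- bact[substr(bact, best$pos, best$pos) == best$res]
    }
    motif <- paste(pattern, collapse = "")
    if (motif == "......n......") break
    found <- c(found, motif)
    pool <- pool[!.matchMotif(pool, motif)]
  }
  found
}

# TRUE for windows matching the motif pattern. '.' is a wildcard (matches
# pads too); residue letters match exactly, so a pad '-' never satisfies a
# residue letter; position 7 must be 'n'.
.matchMotif <- function(windows, motif) {
  chars <- strsplit(motif, "")[[1]]
  hit <- rep(TRUE, length(windows))
  for (p in seq_len(13L)) {
    if (chars[p] == ".") next
    ch <- substr(windows, p, p)
    hit <- hit & if (chars[p] == "n") ch == "n" else ch == chars[p]
  }
  hit
}

.checkWindows <- function(windows) {
  if (any(nchar(windows) != 13L)) stop("windows must be 13 characters")
  if (any(substr(windows, 7, 7) != "n")) {
    stop("window centre must be the site Asn rendered 'n'")
  }
  invisible(TRUE)
}

.checkMotif <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  if (length(chars) != 13L) stop("motif must be 13 characters: ", motif)
  if (sum(chars == "n") != 1L || chars[7] != "n") {
    stop("motif must have exactly one 'n', at the centre: ", motif)
  }
  ok <- chars %in% c(".", "n", .AMINO_ACIDS)
  if (!all(ok)) stop("illegal motif character in: ", motif)
  TRUE
}
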