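# Shared helpers: brute-force oracles and small random fixtures.

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# position-by-position sequon scan, independent of the regex path
bruteForceSequons <- function(seq, allowProlineX = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- integer()
  for (i in seq_len(max(n - 2L, 0L))) {
    if (chars[i] != "N") next
    if (!chars[i + 2L] %in% c("S", "T")) next
    if (!allowProlineX && chars[i + 1L] == "P") next
    hits <- c(hits, i)
  }
  hits
}

# regex-free motif match count for the oracle-equivalence tests ('.' is a
# wildcard; residue letters and 'n' must match exactly, so pads fail them)
bruteForceMotifCount <- function(windows, motif) {
  mc <- strsplit(motif, "")[[1]]
  sum(vapply(windows, function(w) {
    wc <- strsplit(w, "")[[1]]
    for (p in 1:13) {
      if (mc[p] != "." && wc[p] != mc[p]) return(FALSE)
    }
    TRUE
  }, logical(1)))
}

# uniform-random 13-char windows with 'n' centre (valid site windows)
randomWindows <- function(n) {
  vapply(seq_len(n), function(i) {
    w <- sample(AA20, 13, replace = TRUE)
    w[7] <- "n"
    paste(w, collapse = "")
  }, character(1))
}

# deterministic homolog-family fixture: query with two sequons, nHom rows,
# sequon 1 destroyed in the first `broken1` homologs, sequon 2 in `broken2`
conservationFixture <- function(nHom = 20, broken1 = 2, broken2 = 1) {
  query <- paste0(
    "MKLVAAGGHH", "NAT", "PQRSTVWYLK", "NGS", "AADDEEFFHH"
  )
  rows <- c(query = query)
  for (h in seq_len(nHom)) {
    chars <- strsplit(query, "")[[1]]
    if (h <= broken1) chars[11] <- "D"   # sequon 1 Asn at 11
    if (h <= broken2) chars[24] <- "D"   # sequon 2 Asn at 24
    rows[paste0("hom", h)] <- paste(chars, collapse = "")
  }
  homologAlignment(rows, queryId = "query")
}
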