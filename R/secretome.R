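## Spectral-count secretome summaries: per-condition detection overlaps,
## CAZy class/family proportions with the <2 % display filter, and
## top-protein rankings per functional group.

#' Build a protein-by-condition detection table from peptide evidence
#'
#' Sums spectrum counts per protein per condition.
#'
#' @param evidence peptide-evidence data.frame.
#' @param normalize if \code{TRUE}, scales each condition's counts so all
#'   condition totals match the overall mean total (total-sum scaling, the
#'   usual spectral-count "quantitative value" normalisation).
#' @return data.frame with \code{protein_id} and one numeric column per
#'   condition.
#' @export
detectionTable <- function(evidence, normalize = FALSE) {
  tab <- tapply(
    evidence$spectrum_count,
    list(evidence$protein_id, evidence$condition),
    sum, default = 0
  )
  out <- data.frame(
    protein_id = rownames(tab),
    as.data.frame.matrix(tab),
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE
  )
  if (normalize) {
    condCols <- setdiff(colnames(out), "protein_id")
    totals <- colSums(out[condCols])
    target <- mean(totals)
    for (cc in condCols) {
      if (totals[cc] > 0) out[[cc]] <- out[[cc]] * target / totals[cc]
    }
  }
  out
}

#' Per-condition detection counts and overlap regions
#'
#' A protein is detected in a condition iff its count is > 0. Returns all
#' 2^k - 1 Venn region counts (exclusive regions) plus per-condition totals.
#'
#' @param table detection table from \code{\link{detectionTable}}.
#' @return List: \code{per_condition} (named detected totals),
#'   \code{regions} (data.frame with one logical column per condition and
#'   \code{count}; rows are the exclusive regions), \code{n_detected}
#'   (proteins detected anywhere; equals the sum of region counts).
#' @export
conditionOverlap <- function(table) {
  condCols <- setdiff(colnames(table), "protein_id")
  if (!length(condCols)) stop("no condition columns")
  det <- as.matrix(table[condCols]) > 0
  perCondition <- colSums(det)
  membership <- apply(det, 1, paste, collapse = "")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(condCols)))
  colnames(combos) <- condCols
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  key <- apply(combos, 1, paste, collapse = "")
  counts <- table(factor(membership, levels = key))
  regions <- cbind(combos, count = as.integer(counts))
  rownames(regions) <- NULL
  list(
    per_condition = perCondition,
    regions = regions,
    n_detected = sum(rowSums(det) > 0)
  )
}

#' CAZy class and family proportions of spectrum counts
#'
#' Within each CAZy class (GH, CE, PL, AA, ...), the percentage of summed
#' spectrum counts per family. Families below the display threshold are
#' aggregated into "other" in the display table but preserved in the full
#' table; the threshold is inclusive (a family at exactly
#' \code{minDisplayPct} is shown).
#'
#' @param table detection table.
#' @param annotations annotation table (\code{protein_id},
#'   \code{cazy_family}; ";"-joined multi-family labels use the first
#'   family).
#' @param minDisplayPct display threshold in percent (default 2).
#' @return List: \code{full} (data.frame class, family, total_count, pct)
#'   and \code{display} (same with sub-threshold families pooled as
#'   "other"). Percentages sum to 100 within each class in \code{full}.
#' @export
classFamilyProportions <- function(table, annotations, minDisplayPct = 2) {
  condCols <- setdiff(colnames(table), "protein_id")
  totals <- rowSums(table[, condCols, drop = FALSE])
  fam <- annotations$cazy_family[
    match(table$protein_id, annotations$protein_id)
  ]
  fam <- vapply(strsplit(fam, ";", fixed = TRUE), `[`, character(1), 1)
  keep <- !is.na(fam) & fam != "non-CAZy"
  fam <- fam[keep]
  totals <- totals[keep]
  cls <- sub("^([A-Z]+).*$", "\\1", fam)
  agg <- stats::aggregate(
    list(total_count = totals), list(class = cls, family = fam), sum
  )
  agg <- do.call(rbind, lapply(split(agg, agg$class), function(d) {
    d$pct <- 100 * d$total_count / sum(d$total_count)
    d[order(-d$pct), ]
  }))
  rownames(agg) <- NULL
  display <- do.call(rbind, lapply(split(agg, agg$class), function(d) {
    low <- d$pct < minDisplayPct
    if (any(low)) {
      other <- data.frame(
        class = d$class[1], family = "other",
        total_count = sum(d$total_count[low]), pct = sum(d$pct[low]),
        stringsAsFactors = FALSE
      )
      d <- rbind(d[!low, , drop = FALSE], other)
    }
    d
  }))
  rownames(display) <- NULL
  list(full = agg, display = display)
}

#' Top proteins per functional group
#'
#' Proteins ranked by total spectrum count (summed across conditions)
#' within each functional group; ties broken by protein id
#' (lexicographic), so the ranking is order-independent.
#'
#' @param table detection table.
#' @param annotations annotation table with a \code{group} column.
#' @param k list length per group (default 10).
#' @return data.frame: \code{group}, \code{rank}, \code{protein_id},
#'   \code{total_count}, one column per condition.
#' @export
topProteins <- function(table, annotations, k = 10L) {
  condCols <- setdiff(colnames(table), "protein_id")
  table$total_count <- rowSums(table[, condCols, drop = FALSE])
  table$group <- annotations$group[
    match(table$protein_id, annotations$protein_id)
  ]
  table$group[is.na(table$group)] <- "other"
  out <- do.call(rbind, lapply(split(table, table$group), function(d) {
    d <- d[order(-d$total_count, d$protein_id), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out[c("group", "rank", "protein_id", "total_count", condCols)]
}
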