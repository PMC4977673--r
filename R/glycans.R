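## Permethylated N-glycan mass arithmetic and MALDI composition assignment.
## Compositions are Hex_n HexNAc_m (mannose and galactofuranose are mass-
## identical, so labels never claim Man vs Galf identity); peaks are singly
## charged sodiated [M+Na]+ ions, the standard species in positive-reflector
## MALDI of permethylated glycans.

#' Theoretical m/z of a permethylated sodiated glycan composition
#'
#' Computed from elemental composition: the free-glycan monoisotopic mass
#' (n_hex * 162.0528 + n_hexnac * 203.0794 + water) plus one CH2 (14.0157)
#' per methylation site, where sites = 5*n_hex + 5*n_hexnac -
#' 2*(n_hex + n_hexnac - 1) (each glycosidic bond removes two sites), plus
#' the Na+ adduct. Equivalently (the residue-shortcut route, used as an
#' internal cross-check): permethylated residue masses Hex 204.0999 and
#' HexNAc 245.1263 plus a 46.0419 end correction.
#'
#' @param nHex number of hexoses (>= 0); vectorised.
#' @param nHexNAc number of N-acetylhexosamines; < 2 is allowed but warned
#'   (not a canonical N-glycan core).
#' @param adduct "Na" (default) or "H".
#' @param reduced if \code{TRUE}, adds the mass of a reduced (alditol)
#'   reducing end: one extra methylation site plus H2.
#' @param route "sites" (default) or "residues"; both give identical values
#'   and exist so the arithmetic can be cross-validated.
#' @return Numeric vector of m/z values.
#' @examples
#' permethylatedMz(5, 2)  # Hex5HexNAc2 + Na ~ 1579.78
#' @export
permethylatedMz <- function(nHex, nHexNAc = 2L, adduct = c("Na", "H"),
                            reduced = FALSE, route = c("sites", "residues")) {
  adduct <- match.arg(adduct)
  route <- match.arg(route)
  if (any(nHex < 0) || any(nHexNAc < 0)) stop("negative residue counts")
  if (any(nHexNAc < 2)) {
    warning("nHexNAc < 2: not a canonical N-glycan core composition")
  }
  n <- nHex + nHexNAc
  if (route == "sites") {
    sites <- 5 * nHex + 5 * nHexNAc - 2 * (n - 1)
    m <- nHex * .MASS_HEX + nHexNAc * .MASS_HEXNAC + .MASS_WATER +
      sites * .MASS_CH2
  } else {
    permHex <- .MASS_HEX + 3 * .MASS_CH2
    permHexNAc <- .MASS_HEXNAC + 3 * .MASS_CH2
    endCorrection <- .MASS_WATER + 2 * .MASS_CH2   # 46.0419
    m <- nHex * permHex + nHexNAc * permHexNAc + endCorrection
  }
  if (reduced) m <- m + .MASS_CH2 + 2 * .ATOM[["H"]]
  ion <- if (adduct == "Na") .ATOM[["Na"]] else .ATOM[["H"]]
  m + ion - .ELECTRON
}

#' Composition label
#'
#' @param nHex,nHexNAc residue counts.
#' @return Character labels of the form "Hex5HexNAc2". Labels use Hex /
#'   HexNAc because mannose and galactofuranose (and GlcNAc/GalNAc) are
#'   isobaric in MS profiling.
#' @export
compositionLabel <- function(nHex, nHexNAc = 2L) {
  paste0("Hex", nHex, "HexNAc", nHexNAc)
}

#' Assign glycan compositions to observed MALDI peaks
#'
#' Each peak is assigned the nearest theoretical permethylated sodiated
#' composition within the mass tolerance, else left unassigned. Ties (two
#' compositions equidistant within tolerance) are broken toward the smaller
#' total residue count and flagged in \code{tie_broken}.
#'
#' @param peaks data.frame with columns \code{mz}, \code{intensity} and
#'   optionally \code{condition}.
#' @param toleranceDa assignment tolerance (default 0.2 Da, MALDI-TOF
#'   reflector).
#' @param hexRange,hexnacRange composition search space (defaults 0..20 and
#'   2..6; Aspergillus N-glycans have been described up to 18 hexoses).
#' @return \code{peaks} with added columns \code{n_hex}, \code{n_hexnac},
#'   \code{composition}, \code{theoretical_mz}, \code{mass_error_da},
#'   \code{tie_broken}; unassigned peaks carry NA. Assignment is
#'   row-order-independent and idempotent.
#' @export
assignCompositions <- function(peaks, toleranceDa = 0.2, hexRange = 0:20,
                               hexnacRange = 2:6) {
  if (toleranceDa <= 0) stop("tolerance must be positive")
  grid <- expand.grid(n_hex = hexRange, n_hexnac = hexnacRange)
  grid$mz <- permethylatedMz(grid$n_hex, grid$n_hexnac)
  grid$total <- grid$n_hex + grid$n_hexnac
  n <- nrow(peaks)
  peaks$n_hex <- NA_integer_
  peaks$n_hexnac <- NA_integer_
  peaks$composition <- NA_character_
  peaks$theoretical_mz <- NA_real_
  peaks$mass_error_da <- NA_real_
  peaks$tie_broken <- FALSE
  for (i in seq_len(n)) {
    err <- abs(grid$mz - peaks$mz[i])
    within <- which(err <= toleranceDa)
    if (!length(within)) next
    best <- within[err[within] == min(err[within])]
    tie <- length(best) > 1L
    if (tie) best <- best[order(grid$total[best])][1] else best <- best[1]
    peaks$n_hex[i] <- grid$n_hex[best]
    peaks$n_hexnac[i] <- grid$n_hexnac[best]
    peaks$composition[i] <- compositionLabel(grid$n_hex[best],
                                             grid$n_hexnac[best])
    peaks$theoretical_mz[i] <- grid$mz[best]
    peaks$mass_error_da[i] <- peaks$mz[i] - grid$mz[best]
    peaks$tie_broken[i] <- tie
  }
  peaks
}

#' Intensity-weighted hexose distribution per condition
#'
#' Relative proportion of total assigned intensity per Hex count within each
#' condition, plus the modal Hex count. Proportions sum to 1 per condition.
#'
#' @param assignments output of \code{\link{assignCompositions}}; rows with
#'   no assignment are ignored. A missing \code{condition} column is treated
#'   as a single condition "all".
#' @return List with \code{proportions} (data.frame: condition, n_hex,
#'   proportion) and \code{modal_hex} (named integer per condition).
#' @export
hexoseDistribution <- function(assignments) {
  if (is.null(assignments$condition)) assignments$condition <- "all"
  ok <- !is.na(assignments$n_hex)
  if (!any(ok)) stop("no assigned peaks")
  a <- assignments[ok, , drop = FALSE]
  props <- do.call(rbind, lapply(split(a, a$condition), function(d) {
    tot <- sum(d$intensity)
    s <- tapply(d$intensity, d$n_hex, sum) / tot
    data.frame(
      condition = d$condition[1],
      n_hex = as.integer(names(s)),
      proportion = as.numeric(s),
      stringsAsFactors = FALSE
    )
  }))
  rownames(props) <- NULL
  modal <- vapply(split(props, props$condition), function(d) {
    d$n_hex[which.max(d$proportion)]
  }, integer(1))
  list(proportions = props, modal_hex = modal)
}
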