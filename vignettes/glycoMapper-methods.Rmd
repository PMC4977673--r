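---
title: "Methods: mapping N-glycosylation sites in a fungal secretome"
author: "glycoMapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping N-glycosylation sites in a fungal secretome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMapper)
```

# Overview

`glycoMapper` implements the computational core of a secretome
N-glycoproteomics study: given secreted protein sequences, peptide-level
LC–MS/MS evidence, homolog alignments and MALDI glycan peak lists, it maps
which Asn-X-Ser/Thr sequons are actually glycosylated, characterises the
sequence context of glycosylated sites, measures how well sites are
conserved across homologs, and profiles the released N-glycan pool. The
upstream wet-lab and third-party computations — glycoprotein enrichment,
Endo H/PNGase F chemistry, database search scoring, signal-peptide and
CAZyme annotation, BLAST homolog retrieval, alignment construction — are
treated as inputs, not reimplemented.

# The site model and its assumptions

An acceptor sequon is Asn-X-Ser/Thr. Two assumptions are built in:

* **X ≠ Pro by default.** The eukaryotic oligosaccharyltransferase does
  not glycosylate N-P-S/T, so the strict rule is the default; the
  `allowProlineX` flag restores the literal reading, and the strict scan's
  sites are always a subset of the relaxed scan's.
* **Sequons truncated by the C terminus are not sites.** A terminal
  "...NA" or "...NS" has no +2 residue and is never reported.

Each site is classified against peptide evidence into exactly one of three
classes. The partition is presence-based: a single tagged observation
(GlcNAc remnant, +203.0794 Da, on the site Asn) suffices for *validated*.
Probability-based localisation scores are upstream search-engine
computations; as a coarse stand-in for a stricter localisation filter, the
classifier exposes `minTagged` (default 1) and can weight by spectrum
count. Coverage uses Asn containment: a peptide whose interval merely
abuts the Asn does not cover it. Evidence claiming a GlcNAc remnant on a
residue that is not a sequon Asn is inconsistent with the modification's
chemistry and is warned about and ignored rather than silently absorbed.

Sites on non-secreted proteins are retained in the table (the secretion
flag is annotation input); a funnel that filters on signal peptides
operates upstream.

# Mass bookkeeping

All masses are monoisotopic — a 10 ppm precursor-tolerance regime makes
average masses meaningless. Peptide mass is Σ residue masses + water +
modification deltas; the three supported deltas are GlcNAc remnant
+203.0794 (Asn), carbamidomethyl +57.0215 (fixed, Cys) and oxidation
+15.9949 (variable, Met). Digestion follows trypsin's K/R-not-before-P
rule with a configurable missed-cleavage cap (default 1); zero-missed
peptides tile the protein exactly, which is the invariant the test suite
leans on. Peptide length bounds (default unbounded in `digestProtein`,
5–60 would be a typical observability window) are left to the caller
because detectability modelling is out of scope.

Permethylated glycan m/z is computed from elemental composition twice, by
design: once counting methylation sites
(5·nHex + 5·nHexNAc − 2·(nHex + nHexNAc − 1), each glycosidic bond
removing two sites) and once via permethylated residue masses
(Hex 204.0999, HexNAc 245.1263, end correction 46.0419). Both routes are
derived from the same atomic masses, agree to < 1e−12 Da over
Hex0–20 × HexNAc2–6, and exist so the arithmetic cross-validates itself.
The adduct is [M+Na]⁺ (singly charged, electron mass subtracted) — the
species that dominates positive-reflector MALDI of permethylated glycans;
the producing instrument's adduct is rarely stated in publications, so
this is a documented convention, not a measurement.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `allowProlineX` | FALSE | – | OST specificity; flag restores literal N-X-S/T |
| `halfWidth` | 6 | residues | ±6 window standard in sequon-context analyses |
| `maxMissed` | 1 | cleavages | typical search setting for tryptic digests |
| `minTagged` | 1 | observations | presence-based validation definition |
| `toleranceDa` | 0.2 | Da | MALDI-TOF reflector accuracy at m/z 1500–4000 |
| `hexRange` | 0–20 | residues | fungal high-mannose glycans described up to 18 Hex |
| `windowTol` | 0 | columns | strict column identity; >0 tolerates gap shifts |
| `minDisplayPct` | 2 | % | display filter for family charts; inclusive (≥) |

# The synthetic-data generator

The generator is first-class, tested code; its defaults describe the study
conditions the package emulates — three growth conditions (glucose,
pretreated sugarcane bagasse, xylan), mostly CAZy-annotated secreted
proteins of 200–800 residues, ~1.5 sequons per 100 residues, site
occupancy 0.7, peptide coverage 0.8, one-in-ten missed cleavages,
overdispersed spectral counts, homolog retention 0.9, and a Hex5-dominant
high-mannose pool (flat Hex5–9 in xylan; trace Hex14–17 only in glucose).

Design choices where the published record is silent:

* **Background composition** is uniform over the 20 standard residues —
  a neutral background for motif statistics, deliberately not a natural
  amino-acid frequency model.
* **Sequon planting** works on consecutive 3-residue blocks: each block's
  start is planted with probability q = 3·density/100, making the planted
  count exactly binomial over blocks (the distribution the recovery tests
  check) and making densities above 100/3 per 100 residues infeasible by
  construction. Accidental background sequons are scrubbed by rewriting
  their +2 Ser/Thr to Ala — a substitution that can destroy but never
  create a sequon — so the emitted inventory equals the planted truth.
* **Occupancy** is drawn once per site as the ground-truth label; every
  observed peptide covering an occupied site carries the tag. The
  validated fraction of covered sites is therefore a binomial estimator
  of occupancy, which is what the recovery tests assert.
* **Spectrum counts** follow a Poisson–gamma (negative binomial) model
  with per-protein, per-condition log-normal abundances; spectral
  counting is overdispersed in practice and no published count model
  exists for this design.
* **Homolog families** are mutated copies of the query: background
  substitutions at 5 % outside sequon columns, per-site retention draws
  (non-retained sequons lose their Asn), and per-column deletions at the
  indel rate that spare retained sequons, so retention is measured
  exactly by strict-column conservation.
* **The `"nidulans151"` preset** reproduces the composition of a
  151-window validated-site dataset: 42 N-X-S and 109 N-X-T windows with
  19 Gly, 12 Thr and 14 Ser at the X position among the N-X-T windows.
  Only those counts are constrained; all other positions are uniform
  random under a fixed seed, and windows are treated as unique sites.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real flanking-sequence composition biases
(uniform flanks make motif enrichment conservative), homology-driven
peptide ambiguity and protein inference, FDR structure of search results,
retention-time and detectability effects, glycan microheterogeneity per
site, and isotope envelopes or in-source decay in MALDI spectra.

# Numerical conventions

* Coordinates are 1-based everywhere, including alignment columns
  (a gapless query maps position p to column p); file headers state this.
* Windows and motifs are 13 characters with `n` at index 7; `'.'` in a
  motif is a wildcard, while residue letters never match the `'-'` pad,
  so terminal padding cannot satisfy an explicit residue constraint.
* Percentages are displayed to one decimal (so 109/151 renders 72.2);
  unrounded values are kept alongside (`dataset_pct_exact`).
* Glycan assignment takes the nearest composition within tolerance; an
  exact tie is broken toward the smaller total residue count and flagged.
  Assignment is idempotent and independent of peak order.
* Degenerate inputs: empty window sets, zero-coverage evidence and
  all-zero glycan weight vectors are rejected with explicit errors rather
  than propagating NaNs; a `nHexNAc < 2` composition is computed but
  warned about (not a canonical N-glycan core).
* Each generator entry point seeds its own RNG stream derived from the
  config seed (offsets 0–3; homolog families add a hash of the protein
  id) and restores the caller's RNG state, so results do not depend on
  call order and a fixed config is byte-identical across runs.

# Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
statistical checks sharp while staying desk-scale: ~10,000 simulated
sites (350 proteins of 600–1200 residues) for the partition property,
≥ 500 covered sites for occupancy recovery against the exact binomial
99 % interval, 1,000 random proteins for digestion tiling, a
105-composition grid and 1,000 noisy peaks for the glycan checks, and
200 families × 20 homologs (4,000 Bernoulli draws per site) for
retention recovery within three standard errors.

# Known limitations

* Rule-based scanning reproduces the sequon inventory, not a neural
  glycosylation-potential score; sites a scoring tool would call
  non-glycosylated are still listed (with their evidence class).
* Headline counts of the emulating study (e.g. 265 proteins, 182 sites)
  depend on unreleased raw spectra and are deliberately not targets; the
  package validates behaviour on synthetic ground truth instead.
* Background percentages in motif reports depend on the background
  protein set supplied; with the Asn-centred-window definition used here,
  the background for `......n.T....` approximates the Thr frequency of
  that set.
* Conservation is measured at the primary-sequence level; sites that
  migrate along the sequence but remain spatially conserved in 3-D are
  only captured through the column tolerance, not structurally.
* Hex vs specific hexose identity (Man/Galf) and glycan topology are
  outside what MALDI composition profiling can resolve; labels and
  outputs never claim otherwise.
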