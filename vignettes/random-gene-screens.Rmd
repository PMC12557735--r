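---
title: "Modelling selection screens of random sequence libraries"
author: "denovoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selection screens of random sequence libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoscreen)
```

## The problem

Random-sequence expression libraries are an experimental model for de novo
gene birth: millions of plasmids, each expressing an insert of `ATG` + 50
random codons + `TAA` behind an inducible promoter, are challenged with a
selective pressure (here, phage infection of *E. coli*), and inserts that
confer survival are read out by deep amplicon sequencing of the surviving
population. `denovoscreen` models every computational layer of such a screen:

* exact combinatorics of the degenerate-codon library designs;
* a synthetic-data generator for library synthesis, multi-round selection with
  planted functional variants, and paired-end sequencing;
* the read-processing pipeline (pair merging, flank-anchored insert
  extraction, greedy identity clustering, frequency-threshold hit calling);
* ORF tools for dissecting protein- vs RNA-level function (start-codon
  knockouts, maximal synonymous recoding, 3' truncation);
* protein-pool characterisation and the plaque/adsorption assay metrics.

## Degenerate-codon designs

A `DegenerateScheme` is a three-symbol IUPAC pattern. The two classic designs
differ deliberately:

* **NNB** (B = C/G/T): 48 codons, all 20 amino acids, a single stop codon
  (TAG), so P(stop) = 1/48 per codon and a 50-codon insert is stop-free with
  probability (47/48)^50 ≈ 0.349. The composition stays close to the natural
  genetic code while early stops are rarer than under NNN.
* **NYN** (Y = C/T): 32 codons, no stops, and only nine encodable amino acids
  (A, F, I, L, M, P, S, T, V) with a strong hydrophobic bias.

Codon sampling is uniform over the expanded codon set. For IUPAC patterns
this equals independent equimolar sampling of each degenerate position, which
is how such libraries are synthesised; we therefore do not model non-uniform
mixed-base ratios. Only the standard genetic code is supported (the host is
*E. coli*). Distributions carry the stop symbol explicitly so that
conditioning on intact ORFs is an explicit, visible step
(`intactOrfProbability()`, `expectedMeanHydrophobicity()`).

```{r}
probabilities(schemeAminoAcidDistribution("NYN"))[c("L", "V", "S", "*")]
encodableAminoAcids("NYN")
```

## What the generator emulates, and what it does not

`generateLibrary()` + `simulateSelection()` + `sequenceReads()` produce data
with the statistical structure the analysis assumes, plus ground truth:

* **Inserts**: `ATG` + n uniform scheme codons + `TAA` (156 nt for n = 50).
* **Synthesis indels**: a Bernoulli fraction of variants (default 5%, the
  rate reported for synthesised oligo pools of this kind) carries one 1-2 nt
  insertion or deletion inside the random region. This emulates
  frame-disrupting synthesis errors without modelling synthesis chemistry.
* **Abundance skew**: pre-selection abundances are log-normal (default sigma
  1), the standard model for amplification skew; sigma is exposed.
* **Selection**: per round, `bottleneck` clones (default 10^6) are sampled
  multinomially and survive clone-level Bernoulli trials --
  `pSurviveFunctional` (default 0.5) for planted variants, `pEscape` (default
  10^-4) for background escape such as chromosomal resistance mutations. A
  structured-medium screen is colony-forming, so survival is a per-microcolony
  coin flip, not a continuous growth-rate model. Two rounds are the default:
  the second round squares the escape probability, which is exactly why
  re-selection minimises false positives. Setting
  `pSurviveFunctional == pEscape` is the neutral calibration configuration.
* **Sequencing**: read pairs are drawn multinomially at the requested depth,
  cover the amplicon from both ends, and acquire independent per-base
  substitution errors (default 10^-3, a typical short-read error rate).
  Quality strings are constant by default; the pipeline uses qualities only
  for merge tie-breaking. The default depth used in our end-to-end checks is
  3x10^6 pairs, at which the 5x10^-5 hit threshold corresponds to about 150
  reads.

Not modelled: PCR-cycle-explicit amplification bias, chimeras, quality decay
along reads, demultiplexing, or the population genetics of escape phage.
Passing recovery tests therefore show that the pipeline is correct under
multinomial sampling with substitution noise and log-normal skew -- not that
it is robust to chimeric reads or to real instruments' error profiles.

## Pipeline numerical choices

* **Merging** reimplements the usual overlap rule: reverse-complement read 2,
  scan overlaps from longest to `minOverlap` (>= 10), accept the first whose
  mismatch fraction is within budget; the statistical significance test of
  dedicated mergers is deliberately not reproduced. At overlap mismatches the
  higher-quality base wins; ties go to read 1, keeping results deterministic.
* **Insert extraction** finds each flank by best ungapped (Hamming) match
  with a per-flank mismatch budget (default 2); ties go to the leftmost
  offset. Coordinates are 0-based half-open; only the forward strand exists
  because amplicons are orientation-fixed by the flanks.
* **Clustering identity** is matches / alignment columns of an end-to-end
  Needleman-Wunsch alignment with match +1, mismatch -1, linear gap -2, and a
  deterministic traceback (diagonal > up > left). Dedicated clustering tools
  use slightly different end-gap dialects, so the threshold (default 0.95) is
  a parameter rather than a compatibility promise. Sequences are processed in
  decreasing count order (ties lexicographic) and join the earliest-founded
  centroid at or above threshold. An 8-mer counting bound -- an alignment with
  D non-match columns destroys at most 8D of a query's k-mer tokens, and
  D <= (1 - t)(L_q + L_c) -- prunes only centroids that provably cannot pass,
  so the result is identical to the unfiltered greedy scan while scaling to
  hundreds of thousands of unique reads.
* **Hit calling** operates on clusters (summed member counts), making calls
  robust to sequencing errors; raw-level calling is available by flag. The
  threshold comparison is inclusive (>=): at a depth where threshold x total
  is integral this reproduces the "at least N reads" phrasing exactly
  (146 reads at 5x10^-5 of 2.92 million).
* **Enrichment**: post clusters missing from the pre population get the
  frequency floor 1/(pre total + 1) so fold changes stay finite, and are
  flagged as de novo appearances.

## ORF tools

ORFs run from an allowed start codon (ATG, or the bacterial alternatives TTG
and GTG; rarer initiators like CTG/ATT are ignored) to the first in-frame
stop, translate their first codon as Met, and are reported for all three
forward frames including nested starts sharing a stop.

Two design procedures are codified where the underlying lab practice is
usually ad hoc:

* **Start knockout** replaces the start with a minimal-edit codon that is
  neither an allowed start nor a stop. Ties prefer transitions over
  transversions, then the lexicographically smallest codon; this makes
  ATG -> ACG, the classic knockout, and keeps the choice deterministic.
* **Maximal synonymous recoding** replaces each codon by the synonym with the
  most nucleotide differences (ties: lexicographically smallest). The start
  codon is always kept, so initiation is preserved even for TTG/GTG starts;
  Met and Trp have no synonyms and stay; stops are recoded (to another stop)
  only on request. Maximising substitutions maximally disrupts putative
  RNA-level features while the protein is untouched, which is the point of
  the protein-vs-RNA dissection. Whether rare codons should be avoided is
  left open; the objective here is purely edit-maximal.

## Protein pools and effect sizes

Pools default to a 30-residue inclusion floor. Residue classes are fixed and
documented: nonpolar {A V L I M F W P G}, charged {D E K R}, polar-uncharged
{S T N Q C Y H} (glycine and proline counted nonpolar, histidine uncharged).
Mean hydrophobicity is the Kyte-Doolittle average (GRAVY); windowed profiles
default to window 9, a reasonable scale for ~50-residue proteins, with the
conventional 1.0/1.6 moderate/strong thresholds exposed.

`comparePools()` reports Cohen's d with the (post - pre)/pooled-SD sign
convention and a two-sided Welch t-test -- pool sizes in these screens differ
by almost two orders of magnitude (e.g. 151 vs 10,000), so the equal-variance
t-test would be inappropriate. No multiple-testing correction is applied by
default (raw p-values are reported; Benjamini-Hochberg is available). Metrics
with |d| > 0.2 are flagged.

A useful calibration: with no planted compositional difference, pools of 151
vs 10,000 proteins give d values with SD ~= sqrt(1/151 + 1/10000) ~= 0.08, so
|d| < 0.2 should hold in the large majority of neutral replicates -- the
acceptance suite verifies >= 95% over 100 replicates.

## Assay metrics

`plaqueLawnRatio()` is the mean intensity within a plaque mask divided by the
mean within a lawn mask (median available via `fun`); 1 means no visible
clearing (near-complete defense), 0 a fully cleared plaque. The ratio is
invariant to uniform rescaling of the image.  `adsorptionEfficiency()` is
exactly (PFU_control - PFU_sample)/PFU_control x 100%; negative values
(sample above control) are reported as-is with a warning, and timecourses
report adsorbed and remaining percentages that sum to 100 exactly.

## Problem sizes used in the checks

The test suite and acceptance script run the full pipeline at 5,000 variants,
1% planted functional, two rounds with a 10^6-clone bottleneck, and 3x10^6
read pairs, repeated over 5 seeds (median sensitivity and false-discovery
proportion are reported); the neutral-pool calibration uses 100 replicates at
pool sizes 151 vs 10,000. These sizes were chosen so a laptop-scale run
exercises the same frequency regime as a real screen (a hit threshold of
5x10^-5 corresponding to ~150 reads).

## Known limitations

* The merge rule collapses perfect repeats (a longer exact overlap wins), as
  any overlap-maximising merger does; random-codon inserts are essentially
  never repetitive, but homopolymeric amplicons would be.
* Greedy clustering is order-dependent by design (that is the algorithm being
  modelled); the count-then-lexicographic tie-break makes it reproducible.
* The identity dialect differs from specific external tools in end-gap
  handling; thresholds tuned against those tools may need adjustment.
* The composition sampler `randomProteins()` draws residues i.i.d. from the
  scheme's conditional distribution; it models composition, not codon-level
  autocorrelation (there is none under uniform codon draws) nor indel-induced
  frameshifts.
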