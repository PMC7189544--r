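---
title: "Models and methods: ERE expression atlases and ereMAP discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ERE expression atlases and ereMAP discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
rules it implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design choices made where the
underlying procedure left them open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The tissue-specificity model

Family-level expression is the sum of member-transcript TPM
(`aggregate_expression()`), collapsed per tissue to the median across
that tissue's samples (`median_profile()`; even sample counts use the
mean of the two central values). On a per-tissue profile `v` over `N`
tissues the τ index is

τ = Σᵢ (1 − xᵢ) / (N − 1), with xᵢ = vᵢ / max(v).

τ is scale-free: a uniform profile scores 0, a single-tissue profile
scores 1, and the two working regimes are τ ≤ 0.4 (housekeeping-like)
and τ ≥ 0.8 (tissue-restricted, the `call_restricted()` default).
Overexpressing tissues come from the max-gap binarization: sort tissues
by expression, compute neighbour differences, and mark everything above
the largest gap. Two deliberate policies:

* **Equal maximal gaps** resolve toward the top of the ranking, i.e.
  fewer overexpressing tissues. This is the conservative direction for
  specificity and makes the pattern deterministic.
* **Expression floor.** τ is noise-dominated at trace expression (a
  family at 0.01 vs 0.0005 TPM is "specific" but meaningless), so
  features whose maximal median falls below 1 TPM are not called;
  `floor = 0` disables this. Whether the original analysis used such a
  floor is unstated; here it is explicit and tunable.

`quintile_rank()` cuts each family's tissue ranking into five bins. For
32 tissues the sizes are exactly 6, 6, 8, 6, 6; for other N each bin
gets ⌊N/5⌋ with the remainder in the middle bin, which reproduces the
32-tissue scheme as a special case. Ties are broken by stable tissue-id
order and flagged.

`cluster_tissues()` clusters tissue columns of the row-Z-score matrix on
Euclidean distance. The linkage is average by default and configurable:
the distance is prescribed, the linkage is not. Cluster support is the
plain bootstrap proportion over feature resampling (default 1000
iterations); the multiscale/AU correction of dedicated clustering tools
is out of scope, so supports here are ordinary bootstrap probabilities
and should be read as such. Columns are sorted lexicographically before
clustering so distance ties break deterministically.

## 2. The proteogenomic cascade

`call_eremaps()` wires the stages in a fixed order; each discarded
candidate carries exactly one terminal (stage, reason) pair in the audit
table:

1. **Target-decoy FDR (5%).** The threshold is the minimal score `t`
   with `#decoys ≥ t / #targets ≥ t ≤ q` (ratio estimator; the search
   engine's own FDR machinery is not reproducible from tables alone).
2. **Binder filter.** 8–11-mers with best percentile rank ≤ 2% across
   the sample's alleles; both bounds are read inclusively and missing
   per-allele ranks are ignored.
3. **Status.** A peptide seen only in the six-frame ERE read proteome is
   "yes", only in the personalized canonical proteome "no", in both
   "maybe"; "neither" signals a search/proteome mismatch and is
   discarded with its own reason rather than silently dropped.
4. **Read support.** Candidates must be encoded by more than one read.
   The rule's rationale is sequencing-error control, so it is applied to
   every ERE candidate, "yes" or "maybe" — not only inside the "maybe"
   arbitration where the original text mentions it. (A single-read
   "yes" peptide would otherwise bypass the guard entirely.)
5. **24-mer arbitration for "maybe".** All coding sequences (MCS) are
   recovered from the sample's reads by locating the peptide in the
   translated frames and mapping back to nucleotides. The minimal
   occurrence of an MCS is the minimum over its 24-mers of
   reverse-complement-canonical counts. A peptide is discarded if any
   MCS is canonical-only; otherwise the most abundant MCS (by ERE
   minimal occurrence; ties by canonical occurrence then lexicographic)
   must be ≥ 10× its canonical occurrence, inclusively. "Most abundant"
   is measured on the same minimal-k-mer metric used for the ratio, the
   one measurement the arbitration already defines.
6. **I/L variants.** MS cannot distinguish Ile from Leu, so all 2^k − 1
   variants are searched; a variant present at higher expression
   discards the candidate. Canonical entries compare on transcript TPM
   and ERE entries on supporting reads; the two scales are not
   commensurable, so a canonical-proteome variant facing a read-only
   candidate is treated as higher-expressed (conservative) and the
   conflict flagged.
7. **Locus and orientation.** Exact-match loci of each MCS are found on
   both genome strands. Loci inside repeat intervals define the ERE
   origin; region classification uses precedence CDS > intronic >
   intergenic (CDS = any CDS overlap; intronic = inside a gene body).
   The decision tree: CDS-sense is discarded; intergenic is kept in any
   orientation; intronic is discarded only when simultaneously
   gene-sense, ERE-antisense, and single-ERE-locus. Manual
   genome-browser and spectrum inspection steps are replaced by the
   automated exact-match test; a candidate with no repeat-contained
   locus is discarded as "no clear locus".

Aggregation to non-redundant peptides merges identical characteristics
across samples and keeps conflicting ones as alternatives.
`characterize_cohort()` then computes LINE/LTR/SINE proportions at the
genome (repeat base share), transcriptome (per-sample group TPM share,
averaged) and immunopeptidome levels, region proportions against the
repeat background, the Kendall τ-b between per-family peptide counts and
copy numbers, and the source/non-source expression comparison
(Mann–Whitney).

Open interpretation shipped as an explicit switch: "splicing out
sequences following stop codons" defaults to keeping only the prefix
before the first stop (the literal reading); `splice_mode = "split"`
keeps every inter-stop segment ≥ 8 aa.

## 3. Peptide analytics

* **rphm.** `r_overlap` is the minimal 24-mer occurrence of the MCS in a
  sample's k-mer table, and rphm = r_overlap × 10⁸ / total reads
  (computed in that order so the worked value 3 / 2×10⁸ × 10⁸ = 1.5 is
  exact in floating point). The 10-rphm call compares the tissue mean of
  log₁₀(rphm + 1) against log₁₀(11), matching the log-scale averaging of
  the text; `scale = "linear"` compares mean rphm > 10 instead.
* **Methylation.** Probes within 5000 nt of either end of the coding
  locus, Pearson r per probe across samples.
* **Viral homology.** Exact Smith–Waterman with embedded PAM30 and
  affine gap cost 5 + 2·length replaces heuristic word-seeded search; at
  8–11-mer scale exact DP is strictly more complete than a word-size-2
  heuristic. Per subject the identity value is matches / L_p (the
  printed formula's M_max × L_a / L_p with M_max as an identity
  fraction); the literal formula multiplies a percentage by a further
  100 and is available via `mmax_as_percentage = TRUE`, flagged rather
  than silently resolved. Subject selection maximises the identity value
  (configurable to score-maximal). The bootstrap samples groups of the
  query-set size from the canonical pool without replacement within each
  group (`replace = TRUE` available), and p is the fraction of bootstrap
  means above the observed mean, reported as < 1/n_boot when zero.

## 4. What the generators emulate — and what they do not

`make_tissue_panel()` plants housekeeping families (one baseline across
all tissues) and restricted families (20× the residual level in one
tissue by default), with lognormal sample noise and per-sample
renormalisation to 10⁶. Defaults are the stated world of the atlas:
32 tissues, 200 families, 20 restricted, 5 samples per tissue. The noise
default sdlog = 0.2 (~20% CV between same-tissue samples, a realistic
bulk-RNA-seq replicate spread) is the calibration under which
housekeeping profiles stay in the τ ≤ 0.4 regime that defines them and
restricted profiles sit near τ ≈ 0.93–0.95; at sdlog = 0.3 the
housekeeping τ tail crosses 0.4, which would contradict the planted
labels. The panel does not emulate tissue-correlated expression
programs, so clustering on it tests machinery, not biology.

`make_genome()` lays out + -strand genes (4 × 450 nt exons, CDS from a
planted ATG at exon-1 offset 60) and repeat copies cloned from family
consensus sequences at 5% divergence, 51% of copies intronic to mirror
the genome-wide proportion, plus copies inside exons and four copies
straddling the CDS/intron-1 boundary — the geometry the decision tree's
CDS-sense branch needs.

`make_blcl_readset()` plants, as error-free paired 76-mers: 30 ereMAPs
across intergenic sense/antisense, intronic-sense and
intronic-antisense-multi-locus branches; 30 canonical peptides chained
in-frame behind transcript ATGs; 12 "maybe" cases with ERE:canonical
read counts bracketing 10× (50:4 … 20:2 keep; 9:1 … 8:1 discard); 4
single-read cases; 4 decision-tree discard cases; reversed-sequence
decoys at 1:1; and synthesized binding ranks ≤ 2% (binding predictors
are out of scope — the filter contract is what is tested). Three
constructions keep the planted truth exact:

* Supporting first mates are anchored so the MCS opens the read's
  reading frame (F1 forward / R1 on the reverse complement). Under
  prefix-mode stop splicing a stop codon in the shared upstream flank
  would otherwise delete the peptide from every supporting read at once.
* The "maybe" and single-read loci are excluded from background
  coverage (including uniform background), so minimal k-mer occurrences
  equal the planted read counts exactly.
* After injection, every planted MCS is verified to have exactly its
  intended number of genomic exact-match loci; a collision aborts
  generation rather than corrupting the truth table.

Reads are error-free by default because the more-than-one-read rule
exists to guard against sequencing errors: tests must separate the
rule's behaviour from error simulation. The generator emulates neither
base-call errors, indels, splice-junction reads, nor quality-score
structure; a green recovery test therefore establishes the correctness
of the decision logic on unambiguous evidence, not robustness to noisy
alignments.

`simulate_psm_scores()` draws decoys equinumerous with the incorrect
targets (score mixture π₀ = 0.3 incorrect N(0,1), correct N(3.5,1)) —
the target-decoy premise that random matches accrue at equal rates in
the two databases. With decoys at 1:1 with *all* targets the ratio
estimator is conservative by 1/π₀ and realized false-discovery
calibration cannot be observed.

## 5. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at parse/serialise boundaries.
* Row Z-scores use the n−1 standard deviation; constant rows become
  zeros and are flagged rather than NaN.
* τ of an all-zero profile is an error (undefined), not 0; Kendall and
  Pearson on constant input likewise signal rather than return NA.
* The exact Mann–Whitney p enumerates all C(m+n, m) labelings up to a
  pooled size of 12 (valid under ties); beyond that a tie-corrected
  normal approximation with continuity correction is used, which agrees
  with enumeration to < 0.02 at 6 vs 6.
* `apply_fdr()` scans distinct score thresholds via cumulative counts
  (O(n log n)); the returned attribute records the chosen threshold,
  `Inf` when nothing passes.
* k-mer canonicalisation is the lexicographic minimum of word and
  reverse complement; windows containing N are skipped and the totals
  identity (Σ counts = Σ windows − N-windows) is asserted in tests.
* Smith–Waterman ties are irrelevant to the reported quantities (score,
  matches, alignment length of one optimal traceback); the empty
  alignment (score 0) is returned when no positive-scoring cell exists.

## 6. Known limitations

* The per-record read partition means mates of one pair can land in
  different datasets; containment uses the CIGAR reference span, not
  base-level alignment.
* Canonical translation uses the annotated CDS start when provided and
  falls back to the first AUG; non-coding transcripts without an AUG are
  skipped.
* Bootstrap cluster support is not an approximately-unbiased (AU)
  p-value; values are plain bootstrap proportions.
* The cohort-level genome proportions use repeat base share within the
  supplied annotation, which on synthetic genomes reflects the
  generator's layout, not human genome composition.
* Multi-sample runs share one read set per call; per-sample proteomes
  across a cohort are obtained by calling the pipeline per sample and
  aggregating with `aggregate_nonredundant()`.
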