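---
title: "Mining heat shock protein gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining heat shock protein gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Heat shock proteins (HSPs) are molecular chaperones, classified by
molecular weight into six sub-families — SHSP, HSP40 (DnaJ), HSP60
(GroEL/Cpn60), HSP70 (DnaK), HSP90 and HSP100 (ClpB) — that plants induce
under heat and other stresses and during seed development. Genome-wide
surveys of the family in large plant genomes follow a well-established
recipe: find candidates with two independent lines of sequence evidence,
confirm them by signature-domain content, name them by chromosomal
position, and characterize duplication history, gene structure,
promoters, expression and orthology. `hspminer` implements that recipe as
a reusable, fully tested pipeline, together with a synthetic-genome
generator that knows the ground truth of everything it plants, so every
stage can be validated end to end.

## Identification model

Candidates come from two evidence streams that are then merged:

1. **Profile scanning.** Each signature domain is represented by a
   position-specific scoring matrix (PSSM) built from a seed alignment.
   Column frequencies are estimated with background-proportional
   pseudocounts, `f_a = (n_a + w·bg_a)/(n + w)`, converted to log-odds
   `log2(f_a / bg_a)`, rounded to the nearest half bit and stored in
   half-bit units (the BLOSUM62 scale), with a floor of −10 bits for
   unobserved residues at zero pseudocount weight. Proteins are scanned
   with gapped local profile–sequence alignment (Gotoh three-state
   recurrences; a gap of length *k* costs `open + k·extend`, defaults
   11/1 in half-bit units). Hits are reported greedily by descending
   score with non-overlapping query spans.
2. **Homology search.** Seed proteins (one consensus per signature
   domain) are aligned against the proteome with exact Smith–Waterman
   under BLOSUM62, and hits are kept at E ≤ 1e−4 **and** bit score
   strictly above 100.

Significance uses Karlin–Altschul statistics,
`E = K·m·n·exp(−λ·S)` and `bits = (λ·S − ln K)/ln 2`. For ungapped
scoring systems λ is computed exactly as the positive root of
`Σ pᵢpⱼ exp(λ·sᵢⱼ) = 1` (bracketed root finding to 1e−12) and K by the
standard lattice series approximation (truncated convolution of the score
distribution, 60 terms). Gapped scoring has no analytic theory, so gapped
modes use the field-standard calibrated constants (λ = 0.267, K = 0.041
for BLOSUM62 11/1; λ = 1.28, K = 0.46 for nucleotide +1/−2 with 5/2
gaps). The search space is `m·n` with n the summed database length; no
length-adjustment correction is applied (a documented simplification).
The domain-scan e-value cut-off (1e−4) mirrors the homology cut-off; it
is a package default, surfaced as a parameter.

Merged candidates are *confirmed* by re-checking the domain-hit table:
a candidate with no required signature domain is dropped, so
homology-only hits cannot enter the family.

## Classification and nomenclature

Sub-family calls follow the signature domains: pfam00011 (α-crystallin)
for SHSP, pfam00226 (DnaJ) for HSP40, pfam00118 (Cpn60_TCP1) for HSP60,
pfam00012 for HSP70, pfam00183 for HSP90, and for HSP100 the Clp
machinery set {Clp_N pfam02861, ClpB_D2-small pfam10431, AAA variants
pfam07724/pfam07728}, of which at least two distinct members (a
configurable minimum) must be present — a deliberate relaxation of the
full multi-domain architecture so that degraded copies are still
recognized. HATPase_c (pfam02518) is treated as an *expected auxiliary*
domain of HSP90: its absence is recorded, never disqualifying. A protein
matching the required domains of two sub-families is assigned by the
larger summed bit score, with the conflict flagged; no tie rule is
standard in the field, so the choice is explicit and logged.

Names follow the community convention: per sub-family, genes are sorted
by chromosome in natural order (1A, 1B, 1D, …, 7D) and ascending start
coordinate, and numbered from 1 — "short arm to long arm" is
operationalized as ascending coordinate, since centromere positions are
not inputs. SHSP members are named `TaSHSP<n>`, all others
`Ta<subfamily>.<n>`. Genes with several annotated mRNAs get one name per
isoform (`.k` suffix in annotation order); this reading of the dotted
suffixes seen in published family tables is a documented interpretation,
flagged in the output metadata. Unplaced genes (chromosome "Un") are kept
in the family lists, numbered last, and excluded from positional
analyses. Per-gene exon structure uses the longest annotated transcript.

## Duplication, orthology, synteny

A gene pair is a **tandem duplication** iff both genes share chromosome
and strand, their local-alignment amino-acid identity exceeds 40%
strictly, and strictly fewer than five annotated genes lie between them
(counted over *all* genes, not only family members — the rule says
"genes" without qualification). Identity is the local-alignment percent
identity with alignment columns (gaps included) as denominator, matching
BLAST-style reporting; the denominator convention is configurable because
it feeds the 40% rule. Qualifying pairs are chained transitively; arrays
are the connected components of the pair graph. Both readings of "a
duplication event" — pair count and array count — are reported, since
the field uses both. **Identical duplicates** are pairs of
character-identical proteins within a sub-family, a deliberately
independent detector (no positional rule).

**Orthologs** are top hits of a nucleotide Smith–Waterman search of
progenitor CDS against family CDS, kept at E ≤ 1e−10 and bit ≥ 150, ties
broken by lower E then lexical subject id. The per-chromosome **synteny
fraction** is the number of syntenic ortholog pairs (progenitor gene on
the corresponding chromosome under a user-supplied correspondence map)
divided by the number of family genes on that chromosome.

## Expression, promoters, physico-chemistry

A gene is an expression-defined **pseudogene** iff its TPM summed over
all samples is strictly below 1 (threshold and strictness configurable).
Heatmap-ready scaling centres each gene row and divides by the sample
standard deviation (n−1, the ClustVis convention; population sd is an
option); constant rows become zeros and are flagged. PCA is
column-centred SVD on the samples × genes orientation, with component
signs fixed by making the largest-magnitude loading positive, so results
are invariant under sample reordering; variance explained sums to 100%.

**CARE scanning** counts every (possibly overlapping) occurrence of each
IUPAC-degenerate motif in the 1500 bp promoter, on both strands by
default, with palindromic patterns counted once per position —
exhaustive matching is conservative and oracle-checkable. Promoters are
clipped at chromosome boundaries (a gene at position 1 yields a
zero-length promoter, flagged, not an error). **Molecular weight** is the
sum of average residue masses plus one water; X contributes a
configurable mean residue mass. **Isoelectric point** solves the
Henderson–Hasselbalch net-charge equation by bisection on [0, 14]; the
charge curve is strictly decreasing, so the root is unique. The bisection
converges the bracketing interval below 1e−8 pH, which leaves the
residual charge far below the 1e−4 tolerance even on flat charge curves
(short peptides such as GG). The default pKa set is the IPC
protein-optimized table, with the EMBOSS set as an alternative: web
calculators are not reproducible bit-for-bit, so the table is explicit
configuration.

## The synthetic generator

`generate_dataset()` emits a miniature annotated genome whose defaults
are the package's reference validation conditions: 6 chromosomes × 1 Mb
(named 1A…2D so all three sub-genomes are exercised), 60 family genes in
roughly the sub-family proportions seen in hexaploid wheat
(0.22/0.36/0.13/0.15/0.03/0.11), 140 composition-matched decoys with no
domain, planted domains at 20% per-site divergence, tandem arrays of
2/3/5/7 genes, 20% expression-silent pseudogenes, 12 expression samples
in four tissue groups, and progenitor CDS at 5% nucleotide divergence.
Design points worth knowing:

* **Seed alignments are bundled artificial fixtures** (synthetic by
  construction, one per domain id), keeping the repository download-free;
  the consensus of each alignment doubles as the homology seed protein.
* **Decoys draw residues from a uniform background**, giving E-value
  calibration a well-defined null.
* **Array members** share strand and chromosome and are separated by 0–4
  planted decoys, cycling through the boundary values of the
  "fewer than five" rule. Member 2 of every array is an exact protein
  copy of member 1 (an identical duplicate); later members carry 2%
  substitutions. Non-array family genes are laid out with alternating
  strands and at least two decoys between layout units, which provably
  prevents unplanned pairs from satisfying the tandem rule.
* **Promoter motif counts in the truth table are the actual occurrence
  counts** in the final promoter (planting plus background), recounted
  with an internal matcher that is independent of the scanning code —
  background coincidences therefore never break exactness.
* **Expression rows** are log-normal with group-specific induction
  multipliers (SHSP ×8 in grain, HSP70 ×6 in spike, HSP40 ×5 in leaf,
  HSP100 ×4 in spike), making PCA group structure testable; pseudogene
  rows are uniform draws summing below 0.9.
* Everything is driven by one seed through an isolated RNG stream;
  regeneration is byte-identical, and an impossible layout fails before
  any file is written.

What the generator does **not** emulate: realistic codon usage, splice
signals, homoeologous triads beyond the sub-genome label, compositional
bias of real proteomes, or the correlation structure of real expression
atlases. Passing tests therefore demonstrate correctness of the rules
and algorithms under controlled conditions, not recovery performance on
a real 17 Gb genome.

One validation subtlety: the top hit for the progenitor of an
identical-duplicate twin is score-tied between the two twins, so the
exact planted gene is unrecoverable in principle. Validation counts a
recovered ortholog as correct when the recovered subject's CDS is
character-identical to the planted gene's.

## Validation conditions and problem sizes

`simulate_and_validate()` regenerates the reference bundle, runs the full
pipeline, and scores each stage against truth (precision/recall of
identification, classification accuracy, pseudogene-call accuracy,
tandem-array and identical-duplicate recovery, ortholog top-hit recovery,
CARE-count exactness, and the silhouette of grain-like samples on
PC1–PC2). The test suite exercises the same checks plus per-operation
oracles: a full-DP local-alignment oracle (and Biostrings'
`pairwiseAlignment` as a second independent reference), a bisection
oracle for λ, exhaustive ungapped enumeration for profile scores, a
0.001-step grid search for pI, a position-by-position motif counter, and
a brute-force all-pairs tandem detector. Unit tests run on a smaller
bundle (3 chromosomes × 300 kb, 18 family genes) so the default suite
stays fast; the acceptance checks use the full reference conditions.

## Known limitations

* No heuristic seeding: all alignments are exact DP, fine at desk scale
  but not for a 17 Gb proteome.
* Gapped λ/K are configured constants, not estimated from the data;
  E-values omit length adjustment.
* The HSP100 rule accepts any two distinct Clp-machinery domains, which
  is more permissive than the full five-domain architecture.
* Synteny is orthology-based (top hits on corresponding chromosomes),
  not collinearity-block-based.
* GFF3 support covers gene/mRNA/exon/CDS with ID/Parent attributes only.
* FASTA writers emit no comment header (semicolon comments break
  mainstream parsers); GFF3 and TSV writers carry a tool-version comment
  line.
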