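---
title: "Methods: quantifying an EMS TILLinG screen"
author: "tillingr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying an EMS TILLinG screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillingr)
```

`tillingr` quantifies EMS TILLinG screens: given a mutagenized population,
a target amplicon and a set of detected point mutations, it answers how
dense the mutations are, what they do to the protein, where EMS prefers to
strike, and how large the next screen must be. This vignette records the
models, conventions and design choices behind each stage, including the
ones where the methodological literature is silent and the package had to
commit to a definition.

## Coordinates and gene models

All positions are 1-based, inclusive, gene-local and on the coding strand,
so the compact allele nomenclature (`G1734A`) indexes the gene sequence
directly, introns included. GFF3 input is mapped into this frame by
subtracting the gene feature's start; minus-strand genes are
reverse-complemented at load so no downstream code ever handles strand.

Whether "position 1" of a published gene sequence is the transcription or
the translation start is often unknowable from a screen report. The
`cdsStart` slot (1-based offset of the start codon *within the
concatenated exonic sequence*, default 1) absorbs this: shifting it
re-frames every codon without touching the coordinates of the mutations.

Exon intervals are validated (sorted, non-overlapping, in bounds) and
bookended intervals are merged; truly overlapping exons are rejected
rather than merged, because they usually indicate a malformed annotation
rather than an intended structure. `N` bases are allowed in sequences, but
any codon containing an `N` classifies as `ambiguous` — the package never
guesses a base.

## Effect classification

A substitution is classified by re-translating its codon with the
substitution applied, using the standard genetic code:

* identical amino acid → `silent`;
* premature stop gained → `truncation`;
* any other amino-acid change → `missense`;
* position outside all exons → `intronic`.

Two boundary cases have no class of their own in the conventional
three-way exonic scheme, so they are reported as `missense` with an
explicit `flag`: stop-loss (`stop_loss`) and loss of the start codon
(`start_loss`). This matches variant-annotation practice — a mutated start
codon is a protein change (M1L), not an alternative initiator — and the
test suite's independent re-translation oracle is run with plain-code
translation for the same reason. `splice_adjacent` (position within the
first or last 2 bases of an intron) is informational only and never
changes the class: screens count intron hits simply as intronic.

Heterozygosity is not modeled. Mismatch-cleavage detection sees
heteroduplexes, so one detected lesion is one record regardless of
zygosity.

### Percentages and the rounding convention

All reported percentages use half-up rounding (`roundHalfUp`), never
banker's rounding, at one decimal for class tables. Recomputed percentages
can legitimately disagree with a published table's printed values at the
last digit; `effectSummaryFromCounts(..., printed = )` surfaces such
discrepancies in a `discrepancy` table instead of silently matching them.
The pooled silent fraction 39/141 is a concrete case: it rounds to 27.7%,
while 27.6% has circulated in print.

## Mutation density, load and screen design

Density is expressed the way screens report it: base pairs screened per
detected mutation, `screened_bp = Σ amplicon_length × families` and
`bp_per_mutation = screened_bp / n_mutations`. The 95% interval is the
exact (chi-square form) Poisson interval on the mutation count,
propagated to bp-per-mutation; with zero mutations only a lower density
bound exists and the estimate is flagged accordingly.

Whole-kilobase displays are genuinely ambiguous in the literature: 40,191
bp prints as "1/40 kb" (nearest) while 41,953 bp prints as "1/41 kb"
(floor) in the same report. Both conventions are exposed in `kbDisplay`
and the exact bp figure always accompanies them; nothing downstream ever
consumes the rounded form.

Genome load is the linear extrapolation `genome_size / bp_per_mutation`,
displayed to the nearest thousand above 1,000 — the precision at which
such figures are quoted.

`familiesToScreen` uses the per-family hit probability
`p = (L_target / bp_per_mutation) × f_class`. Two designs are offered:
*expectation* (`⌈1/p⌉`, the families whose expected yield is one hit) and
*confidence* (`⌈ln(1−c)/ln(1−p)⌉`, the smallest n with
P(≥1 hit) ≥ c). Published families-to-screen figures often cannot be
reproduced by either formula (their rounding and fractions are typically
unstated); the package documents its formulas and leaves reconciliation
to the user.

Protein-level *saturation* is another under-specified published quantity.
Two definitions are implemented and named: `residues_hit` (fraction of
amplicon-encoded codons carrying a protein-changing call) and
`distinct_protein_changes` (fraction of all EMS-reachable protein-changing
(codon, alternate-residue) events observed, with the denominator obtained
by exhaustively classifying every exonic G>A and C>T). Neither is declared
"the" published definition.

## Context bias around mutated Gs

EMS alkylates guanine, so every canonical lesion can be oriented so the
mutated base is a G: G>A contexts are taken as-is, C>T contexts are the
reverse complement of the coding-strand triplet. The *expected* pool is
every G on the coding strand plus every C treated as a reverse-strand G,
pooled across all supplied amplicons; the *observed* pool is the oriented
triplet of each canonical lesion. Treating Cs as reverse-strand Gs on the
expected side is forced by self-consistency — the observed side is
strand-normalized, so the expected side must count the same universe —
even though screen reports rarely state this.

Positions lacking a −1 or +1 neighbour are skipped from both tallies;
non-canonical lesions (A/T→G/C) are excluded and counted separately. No
smoothing or pseudocounts are applied: raw counts are reported beside
every frequency so sparse cells (a ratio resting on one observation) can
be judged. Divergence flags are *relative* (|obs−exp|/exp ≥ 0.15 by
default), matching the "1.3×"-style fold language of screen reports; the
threshold is a parameter. Whether intronic Gs/Cs belong in the expected
pool is unstated in the literature; the default includes the full
amplicon, with `exonOnly = TRUE` as the switch.

Ranking uses the observed/expected ratio, descending, ties broken
alphabetically, undefined ratios (expected count 0) last, with a 2-decimal
display column since that is how such tables are printed.

## Pooling

`designPools` implements 1D k-fold pooling only: each family enters
exactly one pool of at most k (default 8), pools fill 96-well plates
row-major with zero-padded labels (`A01`), and the plate count is
`⌈⌈n/k⌉/96⌉`. Fill order is the input order and is recorded in the plate
map, because the original fill order of any given screen is typically
unknown and reproducibility matters more than guessing it. Deconvolution
of a positive well returns the member list flagged
`requires_confirmation`; 1D pooling cannot resolve further, by design.

## Population phenotyping

Family records keep both levels the source data has: per-family counts
(sown, germinated, sterile, category flags) and per-plant intensity
grades (0 = absent, 1 = strongest ... 3 = weakest), serialized as
semicolon-joined integers. A family's grade is the maximum over its
plants — the convention that a family is labeled by its most affected
individual. Denominators are explicit because they differ: phenotype
percentages are over families with at least one germinated plant,
germination failure over all sown families, sterility over all germinated
plants. Concordance frequencies are per-plant, reported at 2 decimals
with the exact fraction alongside, plus a Fisher exact test on the 2×2
plant table as auxiliary evidence (screen reports usually print the
frequencies only).

## The synthetic population generator

The generator exists so that every analysis stage can be exercised and
validated without external sequence data. Its defaults are the conditions
of a realistic flax-scale screen: 3,515 families, one lesion per 41,000
bp, two 2-exon amplicons of 869 and 981 bp with exonic GC 0.50 and 0.525
(intron GC 0.1 lower, reflecting the AT-richness of plant introns),
canonical-lesion fraction 154/155, and context weights equal to the
published NGN observed/expected ratios (`emsTripletBias`), weight 1 for
anything unlisted.

Modeling choices:

* Per-family lesion counts are Poisson with mean
  `amplicon_bp / bp_per_mutation` — lesions are independent events along
  the DNA, and a rate is all a screen reports; this is the minimal model.
* Context weighting redistributes lesions *among* G/C sites (sampling
  sites with probability proportional to the weight of their oriented
  triplet) rather than scaling per-site rates, so the configured total
  density is exactly preserved.
* Exonic sequence is a valid ORF (ATG, stop-free body, terminal stop)
  with internal codons drawn from the 61 sense codons weighted to the
  target GC; this requires the exonic length to be a multiple of 3.
* Detection is a Bernoulli thinning of the truth
  (`detectionSensitivity`); the density estimator deliberately ignores
  detection loss (screens treat detected = present), and the simulator is
  the tool to study that bias.
* One mutation list per family: families are pooled sibling DNA, and
  within-family segregation is not modeled.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: PCR/cleavage chemistry and its
sequence-dependent detection failures, dose–response (kill-curve) biology
beyond a user-supplied dose→density table, M1 chimerism and germline
sectoring, zygosity, and linkage between lesions. Recovery tests
demonstrate internal consistency of estimator and generator, not field
accuracy.

## Numerical choices and problem sizes

Seeds are mandatory everywhere randomness exists; the three generator
stages derive distinct streams from one seed (offsets 0, 1, 2) so genes,
lesions and phenotype tables can be regenerated independently. Percentage
rounding is half-up (exact halves go up, deterministically); ties in
triplet ranking break alphabetically; degenerate inputs (zero mutations,
empty spectra, zero plants) raise classed errors rather than returning
NaNs, except the zero-mutation density which returns a flagged
lower-bound estimate because a clean screen is a legitimate result.

The shipped validation suite uses problem sizes chosen to make sampling
error negligible relative to the tolerances while keeping runs quick:
exhaustive SNP-by-SNP oracle comparison on ten 120–300 bp genes,
~40,000-lesion null spectra (tolerance ±0.1 on ratios, with per-triplet
sampling error well inside that band), 100 replicate
3,515-family screens for CI coverage (expecting ≥ 90% coverage from a
95% interval), and 3-standard-error bands for realized rates.

## Known limitations

One CDS per gene (no isoforms); no protein-impact scoring (external
PSSM/SIFT-style scores ride along as opaque annotation columns); ±1
context offsets only (wider motif models are out of scope); 2D pooling
schemes not implemented; per-dose density estimation is supported but
cannot be validated against published per-dose figures, which omit the
per-dose screened-family counts they would require.
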