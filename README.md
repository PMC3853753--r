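# tillingr

Quantitative analysis of EMS-mutagenized TILLinG populations in R.

TILLinG (Targeting Induced Local Lesions in Genomes) finds point mutations
in a chosen gene within a chemically mutagenized population: M2 families are
pooled, a target amplicon is PCR-amplified, and mismatch cleavage (or
sequencing) reveals which pools carry a lesion. EMS produces almost
exclusively G/C→A/T transitions, so the downstream questions are
statistical: how many mutations per kilobase did the screen find, how many
does that imply genome-wide, what fraction of exonic lesions are silent /
missense / truncation, does the local sequence context bias where EMS
strikes, and how many families must be screened to find a knockout of the
next target?

`tillingr` implements that machinery for researchers running or evaluating
plant TILLinG platforms:

- **Gene models** (`GeneModel`, `loadGeneModel`): gene-local coding-strand
  sequence plus exon intervals from FASTA + GFF3/TSV, with codon access.
- **Effect classification** (`classifyMutations`, `summarizeEffects`):
  silent / missense / truncation / intronic calls by codon re-translation,
  Table-style class percentages, substitution spectra, windowed G+C vs
  mutation density (`windowGCMutations`).
- **Density and design** (`estimateDensity`, `genomeLoad`, `saturation`,
  `familiesToScreen`): bp-per-mutation with exact Poisson 95% CIs,
  genome-load extrapolation, protein-level saturation, and sample-size
  calculations. The per-family hit probability is
  p = (L_target / bp_per_mutation) · f_class, and the expectation and
  confidence designs are ⌈1/p⌉ and ⌈ln(1−c)/ln(1−p)⌉.
- **Context bias** (`contextSpectrum`, `rankTriplets`): expected vs
  observed flanking bases around mutated Gs (C→T lesions strand-normalized
  to G→A), NGN triplet observed/expected ratios with divergence flags.
- **Pooling** (`designPools`, `deconvolvePools`): k-fold 1D pooling across
  96-well plates with plate maps and reverse lookup.
- **Population phenotyping** (`summarizePopulation`, `concordance`):
  phenotype category tabulation, sterility and germination rates,
  genotype–phenotype concordance with Fisher's exact test.
- **Synthetic populations** (`simulationConfig`, `simulateGenes`,
  `simulateMutations`, `simulatePopulationTable`): seeded generators with
  Poisson lesion counts, configurable G/C→A/T fraction, context-weighted
  placement and detection sensitivity, so every stage runs without
  external data.
- **Command line** (`tillingCLI`, `inst/scripts/tilling.R`): `classify`,
  `density`, `context`, `design`, `pools`, `pheno`, `simulate`, `report`
  subcommands writing TSV/JSON plus a run manifest.

## Worked example

A two-amplicon screen of 3,515 families (amplicons of 869 and 981 bp; 76
and 79 mutations found):

```r
library(tillingr)

screen <- data.frame(amplicon = c("CAD", "C3H"),
                     length_bp = c(869, 981),
                     n_families = 3515,
                     n_mutations = c(76, 79))
d <- estimateDensity(screen)
d
#> DensityEstimate: 1 mutation per 41953 bp (1/42 kb nearest, 1/41 kb floor)
#>   155 mutations / 6502750 bp screened; 95% CI [35845, 49428] bp/mutation

genomeLoad(d, 370e6)$display
#> [1] 9000
```

One mutation per ~42 kb screened; over a 370 Mb genome that extrapolates
to roughly 9,000 induced mutations per M2 family. Class percentages from
the exonic calls (here from the published counts 15/51/1):

```r
effectSummaryFromCounts(silent = 15, missense = 51, truncation = 1)$percent
#>     silent   missense truncation
#>       22.4       76.1        1.5
```

How many families to screen for a protein-changing mutation in a 1 kb
exonic target at this density (missense + truncation ≈ 72.4% of exonic
lesions)?

```r
familiesToScreen(bpPerMutation(d), 1000, classFractionPresets()["protein_changing"])
#> [1] 57
```

And a fully synthetic screen, end to end:

```r
cfg <- simulationConfig(seed = 1, nFamilies = 500)
models <- simulateGenes(cfg)
sim <- simulateMutations(models, cfg)
calls <- do.call(rbind, lapply(models, function(m)
  classifyMutations(m, sim$detected[sim$detected$gene_id == geneId(m), ])))
summarizeEffects(calls)
```

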