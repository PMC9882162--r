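# nlrdiv

Linking intraspecies allelic diversity of plant NLR immune receptors to
genomic and epigenomic features.

Plant NLRs (nucleotide-binding, leucine-rich-repeat receptors) split into
two populations within a species: *highly variable* (hv) receptors that
accumulate striking amino acid diversity across accessions, and conserved
non-hv paralogs. `nlrdiv` is an R package for researchers asking what
distinguishes the two groups. It provides the full analysis chain:

* **Classification.** Per-column Shannon entropy
  `H = -Σ p_a log2 p_a` of a population protein alignment; a gene is
  called **hv** when ≥ 10 columns (at ≥ 50% occupancy) exceed 1.5 bits.
* **Population genetics.** Segregating sites `S`, nucleotide diversity
  `π`, Watterson's `θ_W = S/(a1·L)` and Tajima's
  `D = (Π − S/a1) / sqrt(e1·S + e2·S·(S−1))` from codon alignments
  (complete deletion) or VCF-derived haplotype matrices
  (pairwise-complete); Nei–Gojobori `πN`, `πS` and `πN/πS` with
  stop-aware pathway averaging; per-domain statistics by majority-vote
  column assignment; 300 bp / 75 bp sliding windows.
* **Genomic features.** TPM from counts and exon-union lengths; gene-body
  CG methylation from Bismark-style cytosine reports (≥ 5-read filter,
  symmetric CG dyad averaging, per-replicate then cross-replicate means);
  distance to the nearest transposable element (0 on overlap); a joined
  per-gene feature table with explicit missing-data flags.
* **Inference.** Wilcoxon rank-sum and Fisher's exact tests;
  label-permutation tests for differences in means/medians (exact
  enumeration when the assignment set is small); covariate-matched
  permutation control; empirical-tail (top/bottom 5%) enrichment tests;
  joint π/D balancing-selection candidates; rank-based gene-set scoring;
  Benjamini–Hochberg adjustment.
* **Synthetic data.** Seeded generators with ground truth for every
  stage: neutral coalescent alignments with known θ, codon populations
  with a tunable nonsynonymous acceptance rate, protein alignments with a
  known number of high-entropy columns, and feature tables with injected
  group effects — plus `runPipeline()`, which chains everything end to
  end.

## Worked example

```r
library(nlrdiv)

# classify a synthetic population alignment with 12 diverse columns
aln <- simulateHvAlignment(nSeqs = 32, length = 120, nVariable = 12, seed = 1)
classifyHv(entropyProfile(aln))
#> HvCall 'gene': hv (12 positions > 1.50 bits; rule >= 10)

# population statistics of a neutral coalescent sample (theta = 5)
pop <- simulateCoalescent(nSamples = 10, theta = 5, lengthBp = 999, seed = 3)
popGenStats(pop)
#> PopGenResult: n=10, sites=999, S=5, pi=0.0016906, thetaW=0.0017692, D=-0.1782

# Nei-Gojobori diversity of a codon alignment
piNpiS(CodonAlignment(c(a = "TTTGGG", b = "TTCGGG")))[c("piN", "piS")]
#> $piN
#> [1] 0
#> $piS
#> [1] 0.75

# end-to-end synthetic run with injected hv effects
res <- runPipeline(list(seed = 7))
res$tests[res$tests$family == "features",
          c("feature", "observed", "p", "p_adjusted")]
#>              feature  observed     p p_adjusted
#> 1      mean_log2_tpm    1.4216 0.001     0.0015
#> 2 cg_methylation_pct  -22.3603 0.000     0.0000
#> 3     te_distance_bp -887.8373 0.022     0.0220
```

The pipeline's confirmatory family reports hv genes more expressed
(positive expression difference), hypomethylated (negative methylation
difference) and closer to TEs (negative distance difference), each with a
one-sided permutation p-value BH-adjusted within the family.

## Package layout

S4 classes with validity checks carry the central objects
(`ProteinAlignment` / `NucAlignment` / `CodonAlignment`,
`EntropyProfile`, `HvCall`, `PopGenResult`, `PermutationTestResult`,
`TailTestResult`); readers cover FASTA, GFF3, TAIR-style TE tables,
Bismark cytosine reports, counts/score TSVs and minimal VCF. See the
methods vignette (`vignettes/nlr-diversity-methods.Rmd`) for the models,
parameter choices and known limitations.
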