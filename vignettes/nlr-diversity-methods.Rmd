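---
title: "Linking NLR allelic diversity to genomic features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking NLR allelic diversity to genomic features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrdiv)
```

## The scientific question

Plant genomes encode hundreds of intracellular immune receptors (NLRs:
nucleotide-binding, leucine-rich-repeat receptors). Within a species, a
minority of them — the highly variable or *hv* NLRs — accumulate striking
amino acid diversity across accessions, while their paralogs stay conserved.
`nlrdiv` implements the analysis chain used to ask what distinguishes the
two classes: how variable is each receptor across a population sample, and
how does that variability co-vary with expression, gene-body CG methylation,
transposable-element (TE) proximity, mutation-probability scores and
population-genetic signatures of selection.

The package has five layers, each usable on its own:

1. **Entropy classification** (`entropyProfile()`, `classifyHv()`),
2. **Population genetics** (`popGenStats()`, `piNpiS()`,
   `slidingWindowStats()`, `domainSubset()`, `statsFromGenotypes()`),
3. **Per-gene genomic features** (`filterAndPairCG()`,
   `geneBodyMethylation()`, `tpmFromCounts()`, `teDistance()`,
   `assembleFeatureTable()`),
4. **Enrichment statistics** (`permDiffTest()`, `matchedPermTest()`,
   `tailCountTest()`, `rankSetScore()`, `balancingSelectionCandidates()`,
   `rankSumTest()`, `fisherTest2x2()`, `bhAdjust()`),
5. **Synthetic data with ground truth** (`simulateCoalescent()`,
   `simulateCodonPopulation()`, `simulateHvAlignment()`,
   `simulateFeatureTable()`), tied together by `runPipeline()`.

## Shannon entropy and the hv / non-hv call

At each column of a population protein alignment we compute
$H = -\sum_a p_a \log_2 p_a$ over the residue frequencies $p_a$; an
invariant column scores 0 bits and a column uniform over $k$ residues
scores $\log_2 k$. A gene is called **hv** when at least 10 columns exceed
1.5 bits, the threshold that separates the bimodal per-gene entropy
distribution seen across the *Arabidopsis* NLRome. The inequality is
strict, and the count is monotone in added high-entropy columns.

Two alignment pathologies need a policy the classification rule itself does
not fix:

* **Gaps and unknown residues.** Gap characters and `X` are excluded from
  the frequency tallies. Counting gaps as a 21st state would let indel
  polymorphism masquerade as substitution diversity, and an `X` carries no
  information about which residue is present.
* **Sparse insertion columns.** Columns occupied by fewer than half of the
  sequences (`minOccupancy = 0.5`, exposed as a parameter) are profiled but
  never counted toward hv status, so a private insertion in two sequences
  cannot manufacture ten "diverse" columns.

```{r entropy}
aln <- simulateHvAlignment(nSeqs = 32, length = 120, nVariable = 12, seed = 1)
classifyHv(entropyProfile(aln))
```

## Population-genetic statistics

`popGenStats()` computes, per region, the segregating-site count $S$, the
mean pairwise difference count $\Pi$ (and per-site $\pi = \Pi/L$),
Watterson's $\theta_W = S / (a_1 L)$ and Tajima's
$D = (\Pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}$, with the 1989 constants
retained in the result object for audit.

**Missing-data policy.** For alignment input we use *complete deletion*:
any column containing a gap or IUPAC ambiguity in any sequence is removed
before anything is counted. This keeps every sequence pair on the same site
set, so $S$, $\Pi$ and the variance constants refer to one consistent
sample. Genotype-matrix input (`statsFromGenotypes()`, e.g. from a VCF)
instead uses pairwise-complete sites — per-site
$\pi = \sum_{a<b} 2 n_a n_b / (m(m-1))$ with each site's own called sample
size $m$ — because genome-wide variant data rarely support complete
deletion; $S$ and $D$ then use the median called sample size. The two
policies can give slightly different per-gene numbers on the same locus;
this is inherent, and the alignment policy is the one used for per-gene and
per-domain statistics.

**Degenerate cases.** $D$ is reported as missing, with a reason code
rather than a zero, when $S = 0$, when fewer than three sequences are
available, and when the variance term vanishes — which happens identically
at $n = 3$, where $c_1 = c_2 = 0$.

**Windows and domains.** `slidingWindowStats()` scans 300 bp windows with a
75 bp step (alignment coordinates, 1-based inclusive; a trailing incomplete
window is dropped so window sizes stay comparable), reporting each window
at its nucleotide midpoint. `domainSubset()` assigns each codon column the
domain claimed by a strict majority (> 50%) of the sequences that have a
residue there, after threading each sequence's residue-coordinate
annotation through its alignment gaps; ties and unannotated columns stay
unassigned, so the per-domain subsets plus the unassigned columns always
partition the alignment.

## Nei–Gojobori synonymous and nonsynonymous diversity

`piNpiS()` implements the Nei–Gojobori (1986) counting scheme with the
standard stop-codon refinement: per codon, each position contributes a
synonymous fraction equal to the share of amino-acid-preserving changes
among its non-stop single-base changes (so `syn + nonsyn = 3` exactly);
per codon pair, differences are classified by averaging over all minimal
mutational pathways that avoid stop codons (falling back, flagged, to the
unrestricted set in the rare case that every pathway is illegal). Codons
with gaps, ambiguity or stops are excluded *per sequence pair*, and
$\pi_N$, $\pi_S$ are means over pairs of pathway-classified differences per
averaged site count. Raw proportions are reported — at intraspecies
divergence the Jukes–Cantor correction is negligible — with the correction
available behind a flag. The ratio is undefined (missing) when
$\pi_S = 0$.

```{r ng}
neiGojoboriSites("GGG")
piNpiS(CodonAlignment(c(a = "TTTGGG", b = "TTCGGG")))
```

## Enrichment and selection tests

Group comparisons use the Wilcoxon rank-sum test (exact for small
tie-free samples, normal approximation with tie correction otherwise) and
Fisher's exact test for 2x2 contingency; both delegate to R's reference
implementations behind a validated interface.

The permutation layer is implemented here:

* `permDiffTest()` permutes group labels for a difference in means or
  medians, **enumerating the full assignment set exactly** whenever
  $\binom{n}{n_A} \le 10{,}000$ and falling back to seeded Monte Carlo
  otherwise.
* `matchedPermTest()` draws, per replicate, one control gene per target
  gene from the same covariate decile of the pool (without replacement
  within a replicate), the standard guard against covariate-driven bias —
  e.g. methylation summaries whose precision depends on the number of
  measured CG sites per gene. Strata too small to supply their draws are
  widened to the nearest neighbours with a warning.
* `tailCountTest()` asks whether a gene subset is over-represented at or
  beyond an empirical percentile cutoff of a genome-wide distribution,
  against random same-size gene sets; `balancingSelectionCandidates()`
  intersects the top-5% tails of per-gene $\pi$ and $D$.
* `rankSetScore()` is a deliberately simple rank-mean set score on one
  sample's expression ranking, normalised to $[0,1]$ by its attainable
  extremes; it is tagged as such in its result and is not a
  reimplementation of published bidirectional single-sample scoring.

**p-value convention.** Permutation p-values default to $b/n$ without the
add-one correction, so a reported 0 means "never reached in $n$
replicates"; the $(b+1)/(n+1)$ estimator is available via `addOne = TRUE`
and is the safer choice when p-values feed multiple-testing adjustment.
For statistics not centred at zero under the null (matched means, tail
counts, set scores) the two-sided p-value is twice the smaller directional
tail, capped at 1. Multiple testing uses Benjamini–Hochberg within each
declared family of tests.

**Known limitation.** Matched resampling draws without replacement from a
finite pool, which shrinks the null variance by roughly $1 - (k-1)/(N_\mathrm{pool}-1)$;
with pools of a few hundred genes the test is measurably anticonservative
(we observed rejection 0.08 at nominal 0.05 with a 200-gene pool). At
genome scale (thousands of pool genes against tens of targets, the regime
the test is meant for) the size is nominal.

## What the synthetic data emulate — and what they do not

The generators define controlled conditions with known ground truth:

* `simulateCoalescent()` draws a neutral Kingman genealogy (coalescence
  rate $k(k-1)/2$), Poisson mutations at rate $\theta/2$ per lineage per
  coalescent time unit, infinite-sites placement on a finite sequence
  (collisions are resampled and warned about). Expectations used in tests:
  $E[S] = \theta a_1$, $E[\Pi] = \theta$, $E[D] \approx 0$ with the known
  slight negative bias at small $n$.
* `simulateCodonPopulation()` uses a *star* genealogy: independent
  lineages, uniform single-base proposals, stop-creating proposals
  rejected, synonymous proposals always kept, nonsynonymous kept with
  probability `omegaAccept`. The star shape is a deliberate simplification
  — it keeps the synonymous/nonsynonymous bookkeeping exact and makes
  "neutral acceptance implies $\pi_N/\pi_S$ centred at 1" a clean
  expectation. It does not emulate shared ancestry within the sample, so
  pair statistics are more independent than in real populations.
* `simulateFeatureTable()` draws per-gene features at rosette-leaf-like
  baselines: expression $\log_2(\mathrm{TPM}+1) \sim N(3, 2)$; gene-body CG
  methylation $100 \times \mathrm{Beta}(1.5, 3)$ percent; TE distance
  zero-inflated exponential (point mass 0.25 at 0 — a TE inside the gene
  span — mean 2 kb otherwise); mutation score $N(1, 0.25)$ on a relative
  scale; and a CG-site covariate Poisson-linked to methylation so the
  matched test has real work to do. Group sizes default to 15 hv and 150
  non-hv NLRs in a 2000-gene background. Effects are injected in SD units
  as *exact mean shifts* (the methylation shift re-parameterises the Beta
  mean at fixed concentration rather than clamping, avoiding boundary
  pile-up that would distort the nominal effect size).

Passing tests on these data demonstrate that the estimators and tests do
what their definitions promise under known conditions. They do not
demonstrate robustness to alignment error, reference bias, bisulfite
conversion failure, mappability artifacts, population structure or linked
selection — all properties of real inputs that the generators deliberately
do not model.

## The end-to-end synthetic pipeline

`runPipeline()` chains the stages on seeded synthetic inputs: protein
alignments constructed above and below the hv boundary (stage 1), neutral
coalescent loci with a higher $\theta$ for the hv group (stage 2), a
feature table with injected effects (stage 3), and the test battery
(stage 4). The confirmatory family tests the three directional hypotheses
— hv more expressed, less methylated, closer to TEs — with **one-sided**
permutation difference-in-means tests, BH-adjusted within the family;
two-sided rank-sum and difference-in-medians variants are reported in
separate families. One-sided tests are the appropriate confirmatory form
here and matter in practice: for the zero-inflated TE distances the
pooled-relabelling null is wide, and the two-sided mean test loses roughly
20 points of power against the same alternative.

```{r pipeline}
res <- runPipeline(list(seed = 7))
res$tests[res$tests$family == "features",
          c("test", "feature", "observed", "p", "p_adjusted")]
```

Every stochastic step derives from the single config seed (child seeds are
recorded in the manifest), and a rerun with the same config writes
byte-identical stage TSVs.

## Numerical and design choices, collected

* Complete deletion for alignment statistics; pairwise-complete only for
  genotype matrices. Per-pair codon exclusion in `piNpiS()`.
* $D$ missing-with-reason rather than 0 when undefined; constants kept on
  the result object.
* Strict `> 1.5` bits; occupancy threshold 0.5; `X` and gaps excluded.
* TE distance is the inclusive-coordinate gap length, 0 for overlap *and*
  adjacency; distances are symmetric in which set is "genes".
* TPM uses exon-union effective lengths; replicate averaging is TPM first,
  then $\log_2(\mathrm{TPM}+1)$; methylation averages sites within
  replicate, then replicates, both unweighted.
* Permutation ties count as "as extreme" (comparisons carry a $10^{-12}$
  guard); empirical percentile cutoffs are inclusive.
* Problem sizes for the calibration and recovery suites (chosen once, as
  desk-scale stand-ins for the real data's scale): 2000 neutral coalescent
  replicates at $\theta = 5$, $n = 10$; 200 neutral codon populations of
  32 lineages at 30 proposals per lineage (enough divergence that the
  ratio-of-means bias of $\pi_N/\pi_S$, which scales as the squared
  variation coefficient of $\pi_S$, is well below its standard error); 500
  null datasets per calibration with 200-replicate inner tests; 100
  end-to-end seeds.

## Limitations

* The entropy classification scores alignments as given; it cannot
  distinguish true allelic diversity from paralog mixing introduced
  upstream of the package.
* Nei–Gojobori counting is a counting method, not a codon substitution
  model; at high divergence or strong codon bias a model-based estimator
  would differ.
* `statsFromGenotypes()` treats haplotypes as exchangeable and ignores
  linkage; its $D$ uses a median sample size across sites.
* The matched test's small-pool anticonservativeness noted above.
* Maximum-likelihood site-selection tests, phylogeny inference and read
  processing are out of scope; their outputs are consumed as inputs where
  relevant.

## A note on pathway counting under complete constraint

With `omegaAccept = 0` the codon simulator never retains a nonsynonymous
change, and the retained-change log proves it. The *measured* $\pi_N$ is
exactly 0 as long as no codon is hit at two distinct positions; when two
synonymous hits land in one codon (in the same or different lineages),
Nei–Gojobori pathway averaging can route part of the two-step difference
through a nonsynonymous intermediate (CTA→TTA and CTA→CTC are both
Leu-preserving, but the pathway TTA→TTC→CTC passes through Phe) and
attributes a fractional nonsynonymous difference to the pair. At the
bench densities used here this contributes at most a few $10^{-4}$ per
nonsynonymous site — two orders below the neutral signal — and is a
property of pathway-based counting itself, not of the simulator or the
constraint.
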