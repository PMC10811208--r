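---
title: "Models and methods in herdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in herdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`herdscan` analyses SNP genotype data from populations formed by
crossbreeding two ancestral lineages — the situation of many composite
livestock breeds, where a local lineage has been graded up with an
improver breed for decades. This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Data model

The central container is a plain samples × loci matrix of ALT-allele
dosages in {0, 1, 2, NA}, with an ordered locus table (chromosome,
1-based position, alleles, an optional per-site RMS-mapping-quality
score consumed from the VCF `MQ` INFO field, never computed) and an
optional matching depth matrix. Phase is discarded on input: no stage
here needs it, and the local-ancestry model is genotype-based by
design. Internally all coordinates are 1-based; BED input/output is
0-based half-open, with the conversion confined to the BED reader and
writer (a BED interval [0, 100) covers positions 1..100).

## The synthetic study system

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified.

**Ancestral divergence.** Per-locus ancestral base frequencies are
drawn uniformly on [0.05, 0.95]; each of the two ancestries then gets
a frequency from the Balding–Nichols law Beta(p(1−F)/F,
(1−p)(1−F)/F), so the expectation is p and the variance p(1−p)F. This
model was chosen over coalescent simulation because its analytic
moments — and the fact that Weir–Cockerham FST between the two panels
converges to F — provide free oracles at desk scale. The default
divergence F = 0.2 is in the range typical of well-separated cattle
breeds; the sweep-power study uses F = 0.05 (close breeds) to make
detection non-trivial.

**Crossbred cohorts.** Each individual draws an ancestry-1 proportion
q from a Beta law specified by mean and concentration
(`beta_shapes()`). Each of its two haplotypes is a two-state Markov
chain along each chromosome with stationary distribution (q, 1−q) and
re-draw probability 1 − exp(−dG) per inter-locus genetic distance d
(uniform map, default 10⁻⁸ Morgans/bp = 1 cM/Mb), G generations since
admixture (default 10). A reversible chain with a stationary re-draw
was preferred to an explicit Poisson tract-length process: at this
scale the two are equivalent, and stationarity is immediate, which
makes the pure-ancestry and G = 0 limits exactly checkable. Alleles
are then drawn Bernoulli from the tract ancestry's frequency and
summed into genotypes. The truth set records the per-locus diploid
ancestry dosage; the recorded `q_true` is the realized mean dosage/2,
so the truth identity holds exactly by construction (the Beta draw is
kept separately as `q_param`).

The default cohort means are 0.3722 (crossbred) and 0.9514
(near-pure) for the ancestry-1 lineage — the two lineage mixes the
analysis is designed to recover — with concentrations 10 and 40:
concentration 10 gives an individual-level spread (sd ≈ 0.15) typical
of a population still segregating for ancestry; 40 keeps the
near-pure cohort tight.

**Sweeps and platforms.** An implanted sweep redraws the target
population's genotypes inside a region from frequencies pushed to
0.98/0.02, which depresses per-site diversity to ≈ 2·0.02·0.98 and
raises differentiation there; all other entries are untouched.
Platform effects mask genotypes independently (defaults: 25 % for the
reduced-representation-like cohort, 2 % for the whole-genome-like
samples, marker sets drawn to overlap partially at 80 % each) and
assign zero-truncated Poisson depths (mean 10). Missingness is
missing-completely-at-random; real reduced-representation data are
missing systematically by restriction site, which is a documented
limitation (below).

## Diversity statistics and filters

For a biallelic locus with ALT frequency p over called genotypes:
Ho = n_het/n_called, He = 2p(1−p), Nei's gene diversity 1 − Σfᵢ²
(equal to He here), MAF = min(p, 1−p). PIC is provided in two
variants: the gene-diversity form 1 − Σfᵢ² (default; the printed
formula's exponent is read as r = 2, the standard form, since any
other exponent leaves it dimensionally undefined) and the Botstein
form subtracting 2p²(1−p)². For biallelic loci
PIC_botstein ≤ PIC ≤ He always, and the default PIC caps at 0.5, so a
PIC ≥ 0.4 panel threshold algebraically implies MAF ≥ (1−√0.2)/2 ≈
0.2764. Population summaries are unweighted means over loci with at
least one called genotype; no sample-size correction of He is applied
by default (both variants are computable, but the uncorrected form
matches the population-program output the summary emulates).

Per-site nucleotide diversity uses the unbiased pair-counting form
2·c_alt·c_ref/(c·(c−1)) on called allele counts; window values divide
the site sum by the nominal window size, except terminal truncated
windows, which divide by their actual span (the convention is stated
because tools differ silently here). Windows start at position 1 and
advance by the step to the chromosome end.

Filtering is sequential and order-sensitive in its per-step counts,
so the order is fixed and logged: depth masking (genotypes, not loci)
→ missingness → site quality → MAF. Masking first means completeness
is always evaluated on the post-masking matrix. The filters are
conjunctive, so the *final* locus set is order-invariant — asserted on
random matrices — even though the audit counts are not. Merging two
platform call sets intersects loci on (chromosome, position, REF,
ALT); a shared position with swapped or conflicting alleles is an
error, never a silent strand flip.

## Sweep scanning

Per-site Weir–Cockerham (1984) variance components a, b, c are
computed for the two populations from genotype counts, using observed
heterozygosity and the unequal-sample-size terms; a window's FST is
the weighted ratio Σa/Σ(a+b+c) over its sites (never a mean of
per-site ratios), negative estimates are retained, and a site
contributes only when both populations have ≥ 2 called genotypes.
Z(FST) standardizes window FST by the scan-wide mean and sample
standard deviation (n−1); a constant scan is an error, and
missing windows stay missing. The log2 θπ ratio uses the comparator
population in the numerator, so positive values mark diversity loss in
the putatively selected population; which population that is must be
stated per run and is recorded in the output, because the convention
is otherwise invisible. Windows with zero π in either population are
excluded from ranking and counted.

Outliers are windows at or above the empirical 95 % quantile (linear
interpolation; ties at the threshold included) of *both* statistics,
taken over the retained windows only. Candidate SNPs are the loci in
outlier windows; candidate genes are annotation intervals overlapping
any outlier window by ≥ 1 bp, deduplicated. Enrichment is the
upper-tail hypergeometric probability per term (identical to the
one-sided Fisher test, asserted to 10⁻¹²) with Benjamini–Hochberg
correction across tested terms.

## Population structure

**Distances and trees.** The p-distance d(i,j) = Σ|gᵢ−gⱼ|/(2m) over
pairwise-complete loci is the member of the "Kimura-2P / p-distance"
pair that is defined for genotype codes rather than sequences, which
is why it is the one implemented. Neighbor joining is delegated to
ape's Saitou–Nei implementation behind `neighbor_joining()` (negative
branches clamped to zero); consequently tie-breaking among equal
Q-criterion pairs follows ape's internal order rather than a
lexicographic rule — determinism is unaffected, and the additive-case
tests use matrices with unique optima. Bootstrap support resamples
loci with replacement and counts bipartitions of the full-data tree
across replicate trees; rooting places the root on the outgroup edge.

**GRM and PCA.** The relationship matrix is
G_ij = (1/m_ij)Σ(gᵢ−2p)(gⱼ−2p)/(2p(1−p)) with in-sample frequencies;
missing genotypes contribute zero and shrink the pair's locus count.
The matrix is eigendecomposed as-is — with complete data its row sums
are exactly zero (because p is estimated in-sample), so leading
coordinates are exactly mean-centered without further centering, and
degenerate spectra (e.g. an identity matrix) give equal variance
proportions. Coordinates are eigenvectors scaled by √λ, ordered by
descending eigenvalue, signs fixed by the first nonzero loading.

**Admixture.** The model is the classic binomial likelihood
g_il ~ Bin(2, Σ_k q_ik f_kl) maximized by plain EM on Q and F with
random restarts (default 3, best kept); plain EM was chosen over
quasi-Newton acceleration because the recovery tests show it adequate
at these sizes, and its monotone-likelihood guarantee is itself a
tested invariant (frequencies are clamped to [10⁻⁶, 1−10⁻⁶], which
perturbs monotonicity below the assertion tolerance). K = 1 has the
closed form q = 1, f = p̂. Cross-validation masks a random 1/folds of
the called genotype entries per fold, refits on the rest, and scores
masked entries by squared dosage error ((g − 2d)/2)²; the loss is
stated because no standard is fixed for it. Label switching is
resolved for evaluation only, by greedy matching of F rows to
reference frequencies.

**Local ancestry.** A diploid HMM over the three unordered ancestry
states {(1,1), (1,2), (2,2)} (implemented over four ordered states and
collapsed). Emissions take panel allele frequencies as Bernoulli
haplotype laws — frequencies at 0 or 1 are clamped to
[1/(2n+1), 1−1/(2n+1)] and the clamping is reported; missing
genotypes emit uninformatively. Per-haplotype transitions re-draw
ancestry from the stationary law (q, 1−q) with probability 1 − exp(−dG)
— exactly the generator's process — and compose into diploid
transitions assuming independent haplotypes. Global proportions are
posterior mean dosages halved (Viterbi paths are available but
posterior means are the default summary). The per-haplotype prior q
defaults to a two-pass scheme: a flat 0.5 pass, then per-individual q
re-estimated from the first-pass dosages; recovery on near-pure
cohorts shows the scheme unbiased to ~10⁻⁴. G is a parameter
(default 10) since the appropriate value is data-dependent and often
unrecorded.

## Core-panel selection

The five steps run in the screening order: depth ≥ 4 (masking
genotypes by default — "filtering out low-depth loci" is ambiguous
between masking and dropping, and masking composes coherently with
the completeness step; a strict `drop_low_depth_loci` mode implements
the other reading), completeness ≥ 0.70, MAF ≥ 0.01, PIC ≥ 0.4
(default variant as above), and removal of intergenic loci, keeping
genic loci and the 5 kb up/downstream flanks. Location classes come
from interval overlap with priority genic > upstream > downstream >
intergenic, strand-aware (unstranded genes treated as plus-strand).
This four-class scheme is a deliberate simplification of
transcript-aware annotation (no intron/exon/UTR/splice split), so
reported genic fractions aggregate what finer schemes subdivide.

## Problem sizes and tolerances

The test and acceptance workloads are sized for a desk machine:
brute-force oracle equivalence on 100 random 20×50 matrices at 10⁻¹²;
FST consistency on 20,000 loci with 100+100 samples (mean windowed
FST within [0.08, 0.12] of a simulated F = 0.10, null |mean| ≤ 0.01);
sweep power over 20 replicates of a 100 kb sweep on a 2 Mb chromosome
with 4,000 loci at background F = 0.05 (≥ 80 % recovery required, and
false flags outside the region at most three times the nominal 0.25 %
intersection rate); ancestry recovery on 5,000 loci with 30+30 panels
and a 50-individual cohort (population proportions within ±0.03,
per-locus hard-call accuracy ≥ 0.90, admixture MAE < 0.05); and exact
NJ recovery on random additive trees of up to 8 taxa. Determinism is
absolute: one integer seed drives every generator, and repeated runs
are bit-identical.

## Known limitations

- No background linkage disequilibrium beyond ancestry tracts: given
  the tract ancestry, alleles are drawn independently across loci, so
  haplotype-based statistics (XP-EHH, iHS) are out of scope and LD
  pruning is unnecessary on simulated data.
- Missingness is completely at random; platform-specific *systematic*
  missingness (restriction-site dropout) is not modelled, so passing
  tests say nothing about bias from informative missingness.
- The local-ancestry HMM assumes the two haplotypes switch
  independently and panels are the true, unadmixed sources.
- Location classes stop at genic/flank/intergenic; no transcript
  model, no splice/UTR categories, and no gene-length bias correction
  in enrichment (candidate windows are length-biased toward long
  genes, which a length-aware method would correct).
- The generator does not model sample exclusion or relatedness within
  cohorts (all individuals are exchangeable draws).
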