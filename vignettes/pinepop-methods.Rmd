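---
title: "Methods: population genomics and SNP panel design for clonal germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics and SNP panel design for clonal germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinepop)
```

# Scope and data model

`pinepop` analyses multi-sample SNP genotype matrices from germplasm
collections of clonally propagated crops, with pineapple (*Ananas
comosus*) as the motivating system: a genebank cohort typically mixes
cultivar groups that have been propagated vegetatively for centuries
('Queen', 'Smooth Cayenne', 'Singapore Spanish'), groups with more sexual
history ('Mordilona-related'), wild varieties, and inter-group hybrids.
The package covers the post-variant-calling part of such a study: genotype
recalibration and filtering, per-accession heterozygosity, per-locus
inbreeding coefficients, windowed Tajima's D, ancestry-threshold
population assignment, design of two diagnostic SNP panels, and classical
MDS of panel genotypes. Read alignment, variant calling and ancestry
(ADMIXTURE-style) inference are upstream tools whose outputs (VCF, BED,
`.Q` files) are consumed, not reimplemented.

The central container is the `genotype_matrix`: accessions x loci dosages
of the alternate allele (0/1/2, `NA` for missing), locus coordinates, and
an optional read-depth matrix. Genotypes are unphased and half-calls are
treated as missing, since no statistic here uses phase. VCF positions are
1-based; BED intervals are converted once at the boundary from their
native 0-based half-open convention.

# Missing-genotype recalibration

When per-sample VCFs are merged, an accession that simply matches the
reference at a site contributes no record and surfaces as a missing
genotype. `recalibrate_missing()` rescues such calls using read depth:
a missing call backed by at least `min_depth` reads (default 5) becomes
homozygous reference; lower-depth missing calls stay missing, and
non-missing calls are never touched. The rule is deliberately minimal and
configurable; a depth threshold of 5 gives a reference miscall rate below
about 3% for a heterozygous site under binomial sampling of alleles. The
known cost is that true non-reference genotypes hidden behind merge
artefacts are imputed as reference, which inflates homozygosity slightly
and biases per-locus F~is~ upward in well-covered, high-missingness data;
the pipeline records missing-call counts before and after recalibration
so the effect is auditable.

# High-quality SNP filtering

`filter_high_quality()` removes loci that are non-biallelic, have minor
allele frequency (MAF) below 0.02, or missing-call fraction above 0.10.
Both thresholds are boundary-exclusive — a locus at exactly MAF 0.02 or
10% missingness is retained — and MAF is computed on allele counts (a
`2 * n_called` denominator), the standard definition. Rules are applied
in a fixed order (non-biallelic, MAF, missingness) for the audit report;
the retained set is order-independent and every filter is idempotent.
Loci with zero called genotypes are flagged undefined rather than
silently dropped, so filtering funnels stay conserved
(`input = output + removals`).

# Heterozygosity, F~is~ and Tajima's D

Per-accession heterozygosity is reported as
`100 * n_het / denominator`. The denominator (callable sites per
accession) must come from the caller because it depends on upstream
coverage analysis; without it the package falls back to the total locus
count with a warning, which is comparable within one matrix but not
across datasets.

The per-locus inbreeding coefficient is

$$F_{is} = 1 - \frac{f_{Aa}}{2 f_A f_a},$$

with \(f_{Aa}\) the observed heterozygote proportion and \(f_A, f_a\) the
allele frequencies among called genotypes. Negative values mean
heterozygote excess — the signature of clonal propagation, where the two
alleles of a lineage never segregate and heterozygous sites accumulate
(Meselson-type divergence) — and positive values mean heterozygote
deficit. At loci monomorphic among called genotypes the statistic is
undefined and returned as `NA`; undefined values are excluded from all
means and distribution summaries, never coerced to zero. In a
random-mating sample of *n* diploids the estimator's expectation is
\(-1/(2n-1)\), not exactly zero; tests account for this.

Tajima's D contrasts two diversity estimators over a region: mean
pairwise differences \(\pi\) and Watterson's \(\theta_W = S/a_1\). Because
single SNPs do not define a region, D is computed in non-overlapping
windows (default 10 kb) tiled from position 1 of each chromosome.
Within a window and population, allele frequencies give
\(\pi = \sum_s 2 p_s (1-p_s)\, n/(n-1)\) (the small-sample-corrected,
unphased estimator, exactly equal to averaging over all haplotype pairs),
\(S\) counts segregating sites, and the variance constants
\(a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2\) follow the standard
normalisation. The haplotype sample size per window is fixed at twice the
minimum number of called accessions across the window's loci so the
constants are consistent within a window. Windows with \(S = 0\) or fewer
than four haplotypes are flagged undefined. Positive D indicates a
deficit of rare alleles, as expected under long-term clonality; values
near zero are consistent with neutral random mating.

# Ancestry-threshold assignment

Ancestry tables (Q matrices) at several resolutions K are joined to group
labels in two steps. `map_components()` assigns each group the component
with the highest mean proportion among labelled seed accessions; if two
groups claim one component the higher mean wins and the loser is left
unmapped with a warning — this happens legitimately when K is too small
to separate close groups. `assign_populations()` then labels an accession
with group *g* only when its *g*-component proportion is strictly greater
than the threshold (default 0.70) at **every** supplied K; anything else
is a hybrid. The conjunction over K and the strict inequality make the
rule conservative: raising the threshold can only move accessions from
definitive to hybrid, never the reverse. A practical consequence is that
members of a group that is unseparable at some K (e.g. two wild varieties
merging at K = 5) are conservatively labelled hybrids unless the K set is
restricted to resolutions where the group is distinct.

# Diagnostic SNP panels

Panel A (cultivar identification) applies, in order: (1) removal of SNPs
inside repeat intervals expanded by 100 bp flanks (position-inclusive at
the expanded bounds); (2) deduplication of loci sharing an identical
genotype vector, keeping one chosen uniformly under the recorded seed;
(3) per-group candidate discovery — a locus qualifies for group *g* when
its genotype is uniform across all *g* accessions and differs in at least
one outside accession; (4) ranking by the divergence score, the count of
outside accessions whose genotype differs from the group's shared
genotype, with deterministic (chromosome, position) tie-breaks; (5) top-50
selection per group; (6) merging across groups and distance thinning.
Thinning makes two passes: all members of any same-chromosome pair at
most 100 bp apart are removed (a removal rule, not keep-first), then each
100 kb window anchored at position 1 keeps its highest-scoring entry
(ties to the smallest position). Input matrices are expected pre-filtered
to anchored chromosomes, no missing calls (so every accession contributes
equally) and MAF at or above 0.02.

Two places in this workflow were genuinely open and are worth stating.
First, "uniform within the group and divergent outside" is one of two
defensible readings of cultivar-unique genotypes (the other being
group-private alleles); it is the one that makes the divergence ranking
well-defined. Second, a locus can qualify for several groups at once
(uniform in each, e.g. homozygous-alternate in one group and
homozygous-reference in another); after the per-group top-50 lists are
merged, each locus keeps only its highest-scoring attribution, otherwise
the close-pair removal would annihilate the duplicated coordinates.

Panel B (pedigree analysis) keeps only loci with no heterozygous and no
missing call in any accession, then applies the same deduplication and
distance thinning. The result is a panel of fully homozygous SNPs whose
genotypes are stable under vegetative propagation, suitable for
parent-offspring checks.

`validate_panel()` re-checks the pairwise-distance, one-per-window,
pattern-uniqueness and (Panel B) homozygosity constraints independently
of the construction path.

# Distances and MDS

Distances over panel loci are mean per-locus Manhattan distances between
dosages (`|c_i - c_j| / L`, maximum 2), with a mismatch-proportion metric
as an alternative. `classical_mds()` implements Torgerson scaling:
double-centre the squared distance matrix, eigendecompose, scale the top
*k* eigenvectors by the square roots of their eigenvalues. Negative
eigenvalues among the top *k* (non-Euclidean input) are truncated to zero
with a warning; each axis's sign is fixed by making its
largest-magnitude loading positive so plots are reproducible. Classical
MDS was chosen over stress-majorisation because it is deterministic,
exact on Euclidean-embeddable input, and the embedding is unique up to
rotation.

# The cohort simulator

Because no genotype data ship with the package, every stage is validated
against `simulate_cohort()`, a forward-in-time simulator of partially
clonal populations. Each population starts from founders drawn under
Hardy-Weinberg proportions from an ancestral allele-frequency law and
evolves for T generations: an offspring is, with probability *c* (the
clonality rate), a verbatim copy of a random parent, and otherwise the
union of gametes from two distinct random parents (distinct, mirroring
self-incompatibility in cultivated pineapple). Every offspring is then
subject to heterozygosity-gain mutation (homozygote to heterozygote at
rate mu per locus per generation). Applying mutation to all offspring —
not only clones — keeps mutational input identical across clonality
rates, so that comparisons across *c* isolate the fate of heterozygotes
(segregation versus protected copying); tying mutation to clones would
conflate the two and, at *c* = 0, leave a population with no mutational
input whose drift-dominated site-frequency spectrum masquerades as a
clonality signal.

The default ancestral frequency law is a truncated neutral-like
site-frequency density \(f(p) \propto 1/p\) on \([10^{-3}, 1)\), under
which a random-mating cohort yields Tajima's D centred near zero — the
property that makes the D calibration test meaningful. Uniform and Beta
laws are available for designed fixtures; the panel-recovery fixtures use
Uniform(0.35, 0.65) so that no background locus is close enough to
fixation to mimic a group-diagnostic pattern by chance.

On top of the per-population genotypes the simulator layers: planted
group-diagnostic loci (homozygous-alternate inside the group,
homozygous-reference outside except one rotating heterozygous outside
accession per locus, which keeps the planted columns distinct so the
pattern-deduplication step cannot collapse them while leaving the
divergence score maximal), spaced more than 110 kb apart genome-wide so
distance thinning keeps them all; F1 hybrids built by ancestry-weighted
allele draws; missing calls with correlated read depths (a fraction of
missing calls get depth below 3, the rest keep their negative-binomial
depth so recalibration can rescue them); repeat intervals that avoid
planted loci; and truth-derived Q tables at K = 5, 6, 7 in which each
group owns one component (groups beyond K share the last component, as
real structure inference would merge them at low K).

What the simulator does **not** emulate: linkage and recombination maps
(loci are independent), selection, genotyping error beyond missingness,
and realistic pineapple LD. Passing tests therefore demonstrate that the
statistics and workflows behave correctly under their own model
assumptions — heterozygote excess and rare-allele depletion under
clonality, HWE calibration under random mating, exact recovery of planted
diagnostics — not that any particular real dataset will show those
signals at a given effect size.

# Numerical and testing choices

* Undefined statistics (F~is~ at monomorphic loci, D at S = 0 or under
  four haplotypes) are `NA` and excluded from summaries.
* Q-matrix rows must sum to 1 within 1e-4 and are renormalised exactly;
  allele-frequency identities hold to 1e-12; MDS reconstruction is tested
  at 1e-9 and Procrustes recovery at 1e-8.
* All randomness (pattern dedup, simulation) flows from explicit seeds;
  the pipeline derives per-stage seeds from one master seed, and two runs
  with the same master seed produce byte-identical outputs.
* Validation problem sizes were chosen desk-scale: cohorts of 68-83
  accessions and 2000-5000 loci; the HWE calibration uses founders
  sampled directly from the ancestral law (T = 0, c = 0, mu = 0, n = 30,
  2000 loci, ten seeds); the clonality-signature and monotonicity studies
  run at mu = 1e-3, T = 200, n = 30 with clonality rates {0, 0.5, 1} on a
  common seed grid (1:10), sharing founder draws across rates. The
  monotonicity of D in the clonality rate is a small effect at c = 0.5 —
  partial clonality barely perturbs the gene genealogy until c approaches
  1 — which is why that study uses 4000 loci and paired seeds.
* Heterozygosity percentages depend on the caller-supplied callable-site
  denominator; over SNP matrices alone the values are much larger than
  genome-wide figures and only comparable within a run.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "pinepop-demo", seed = 7)
report <- run_pipeline(cfg)
report$stages$popgen
```

The per-population table separates the clonal groups (strongly negative
mean F~is~, positive mean D) from the sexual ones (mean F~is~ near zero,
mean D near zero), and `panel_A.tsv` / `panel_B.tsv` in the output
directory carry the designed panels with their genotype vectors and the
per-step funnel in `report.json`.

# Known limitations

* The depth-based recalibration imputes reference homozygotes and cannot
  recover hidden non-reference genotypes; its bias is visible in the
  sexual populations' slightly positive mean F~is~ in the demo pipeline.
* Tajima's D windows with very few SNPs are noisy; the window width is a
  tunable compromise and windows are not recentred on SNP density.
* The assignment rule inherits ADMIXTURE's resolution: groups that merge
  at some K cannot be called definitive under the strict conjunction.
* Panel sizes depend on the input cohort; the workflows reproduce the
  procedure, not any particular published panel.
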