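---
title: "Methods: differential methylation and expression analysis of primordial germ cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and expression analysis of primordial germ cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`pgcmethylome` implements the computational core of a comparative
epigenomics study of zebrafish primordial germ cells (PGCs) and their
somatic siblings across early development (4, 7, 24 and 36 hours post
fertilisation), flanked by adult reference methylomes (sperm, oocyte,
brain, liver). Four analysis questions drive the design:

1. Where do PGC and soma methylomes diverge locally? (per-CpG testing,
   DMR stitching, filtering and classification)
2. Which CpG-island promoters are progressively targeted by 5mC during
   development? (the non-methylated-island promoter screen)
3. Which genes mark the PGC transcriptional programme, and are they
   conserved? (stage-wise differential expression, marker rules,
   clustering, cross-species testing)
4. Does exon inclusion differ between germline and soma? (delta-PSI rules
   on percent-spliced-in tables)

Because the study's sequencing data cannot ship with the package, a
seeded synthetic-data generator plants known features — DMRs, 5mC-target
promoters, marker genes, differential exons — in a miniature genome, and
every analysis stage is validated by recovering that truth.

# The per-CpG test and DMR calling

For each CpG covered in both tissues, the methylated read fraction is
compared with a beta-binomial Wald test. Within a group with replicate
counts $(M_r, N_r)$ the pooled mean is $\hat\mu = \sum M_r / \sum N_r$,
and its variance uses a per-CpG overdispersion $\rho$ estimated by the
method of moments across replicates (each group estimates its own
$\rho$, floored at $10^{-3}$ and capped at 0.99):

$$\widehat{\mathrm{Var}}(\hat\mu) =
  \hat\mu(1-\hat\mu)\,\frac{\sum_r N_r\,(1+(N_r-1)\hat\rho)}{(\sum_r N_r)^2},
\qquad z = \frac{\hat\mu_{PGC}-\hat\mu_{soma}}
                {\sqrt{\widehat{\mathrm{Var}}_1+\widehat{\mathrm{Var}}_2}}.$$

Two-sided normal p-values define differentially methylated CpGs (DMCs)
at `alpha_dmc` (default $10^{-3}$; an FDR-gated variant is available via
`fdr_gate = TRUE`). No smoothing across neighbouring CpGs is applied, so
the test is exactly reproducible by a scalar reference implementation —
the property the test suite exploits. The pooled-across-groups moment
estimator was rejected during development: on null beta-binomial data it
is anti-conservative (empirical type-I ≈ 0.078 at nominal 0.05 and 30×
coverage), while the per-group estimator stays within [0.03, 0.07]. The
Wald construction is only approximately calibrated in the extreme tail
(the empirical rate at $p<10^{-3}$ exceeds nominal severalfold); this
does not produce false DMRs because isolated background DMCs cannot form
stitchable runs (below), but `alpha_dmc` should not be interpreted as an
exact per-CpG error rate.

The 4 hpf samples carry *technical* rather than biological replicates,
and `per_cpg_test_technical()` therefore tests each replicate pair
separately with a single-replicate binomial Wald statistic and reports
only CpGs significant in *every* pair with a consistent sign of
difference. Sign consistency is this package's own tightening of the
"commonly identified" intersection rule; without it a CpG significant in
opposite directions would survive as a nonsensical merged DMC.

DMCs within 50 bp of each other are stitched into candidate regions
(`[first−1, last)` half-open, so interval width equals the 1-based
inclusive span). Candidates are then filtered in order:

| rule | default | note |
|---|---|---|
| minimum DMCs | 5 | |
| minimum span | 50 bp | span = end − start |
| repeat overlap | ≥ 1 bp excludes | RepeatMasker-style track |
| low-coverage CpGs | > 25% excludes | pooled within-group coverage < 5× in either group |
| classification | \|Δ\| ≥ 0.1 in *both* replicates | coverage-weighted mean difference |

Candidates passing all filters but failing the two-replicate Δ rule are
retained as `unclassified` and flagged, never silently dropped.

# The promoter 5mC-target screen

Non-methylated islands (NMIs) from several peak files are concatenated
and merged (book-ended intervals merge; the merge is a plain interval
union, so the choice only matters at exact adjacency). NMIs overlapping
a transcription start site by at least 1 bp — no flank — become promoter
candidates. Per candidate and sample, methylation is the
coverage-weighted mean over the island's CpGs, with the pooled
methylated/unmethylated counts retained.

A candidate is a putative developmental 5mC target when all five gates
hold: Pearson correlation of the replicate-averaged somatic stage means
with developmental stage exceeds 0.5; 4 hpf methylation is below 0.025
and 36 hpf methylation above 0.15 *in each replicate*; and adult brain
and liver both exceed 0.45. The correlation uses stage rank (1–4) rather
than hours post fertilisation: "increases with development" should not
depend on the uneven 4/7/24/36 spacing, and a `stage_axis = "hpf"`
switch restores the alternative. Significance of the early→late gain is
a two-sided Fisher exact test per replicate on the pooled counts
(rows = 4+7 hpf vs 24+36 hpf, columns = methylated/unmethylated),
implemented by full hypergeometric enumeration with the
point-probability two-sidedness rule, followed by Benjamini–Hochberg
adjustment *within replicate* across all tested candidates (the family
is the set of islands entering the test, not only gate-passers).
Targets require adjusted p < 0.01 in both replicates; the output keeps
both the gated tier and the gated-and-significant tier.

# Differential expression and marker rules

Counts are compared PGC vs soma per stage with a self-contained exact
conditional test: counts are adjusted to a common library size, pooled
within group, and the split $(A, n-A)$ of the pooled total is referred
to the balanced-split null in which both group sums are negative
binomial with common dispersion,

$$P(A = k \mid A+B = n) \propto f(k)\,f(n-k), \qquad
  f = \mathrm{NB}(\mu = n/2,\ \mathrm{size} = R/\phi),$$

with $R$ replicates per group and per-gene dispersion $\phi$; $\phi = 0$
recovers the exact conditional binomial. $\phi$ comes from a
method-of-moments estimate on the replicates, moderated toward the
common dispersion across genes with `prior_df` (default 20)
pseudo-replicates. Two estimator details matter for calibration at two
replicates per group: the common value is the *unfloored mean* of the
per-gene moment estimates (their median, or a trimmed or floored mean,
is biased low because the estimator is strongly right-skewed at 1 df),
with a second-order correction $d(1+d/2)$ for the random denominator.
So constructed, the test's empirical type-I rate on 10,000 null
negative-binomial genes is ≈ 0.05 at nominal 0.05. A literal
"scaled-binomial" alternative (divide counts by a variance-inflation
factor, then binomial-test) was implemented first and rejected: at
dispersion 0.1 with 2 + 2 replicates it loses roughly 40% of the
attainable z-score and cannot recover planted markers reliably.

Fold changes are `log2((CPM_A + 0.5)/(CPM_B + 0.5))`; a gene is
`up` when log2FC > 1.5 with BH FDR < 0.05 (the mirror image for
`down`). *Consistent markers* are genes up at all four stages;
*consecutive-stage regulators* are genes up in at least two adjacent
stages of (4, 7, 24, 36) — by construction a superset of the markers.
Regulator dynamics are clustered by k-means (k = 5, 50 restarts, fixed
seed) on z-scored per-stage log2FC profiles; genes are sorted before
clustering so input order cannot change the result, and cluster labels
are renumbered by the mean stage of their peak so that label 1 always
means "earliest-peaking". Cross-species conservation maps regulators
through an orthology table, averages log(FPKM+1) over PGC and over soma
samples of each foreign panel, and applies a paired t-test across
genes; a gene is conserved in a species when its PGC mean exceeds its
soma mean, and the high-confidence set is conserved in every species.

# Exon inclusion

Events must reach the `VLOW` read-coverage code in all eight samples
(PGC/soma × 7/24 hpf × 2 replicates). For each of the four comparisons
(tissue at 7, tissue at 24, development within PGC, development within
soma), delta-PSI is computed per replicate pair (replicate i vs
replicate i); an event is differential when |mean dPSI| ≥ 15, each
paired |dPSI| ≥ 5, and the pairs agree in sign. Tissue-marker exons
additionally need |stage-level dPSI| ≥ 10 at both stages with a common
sign, |mean| > 15, and a two-sample t-test p < 0.05 over the four PGC
versus four soma values. All three rule sets are deliberately simple
arithmetic on the PSI matrix, and the suite re-checks every decision
with an independent scalar evaluator.

# The synthetic study design

`sim_config()` defaults define the simulated study; they were fixed
once, from the power analyses described here, before the recovery tests
were written.

* **Genome**: 5 Mb over 2 chromosomes; background CpGs at exponential
  spacing (mean 100 bp). 400 genes; 300 promoters carry an NMI
  (200–1000 bp, CpGs every 10 bp). Repeats cover 10% of the genome and
  never approach planted features, so the repeat filter cannot remove
  truth. Planted regions (20 early-hypo, 25 late-hyper, 40
  developmentally demethylating) are 400–800 bp with CpGs every 5 bp —
  strong CpG-island character. The density is load-bearing: with 50 bp
  stitching, runs can only skip a few missing DMCs when CpGs are ≈5 bp
  apart, and the 100 bp background spacing is *why* isolated false
  DMCs can never stitch into a false DMR.
* **Methylomes**: depth is negative binomial (mean 30×, size 5);
  methylated counts are beta-binomial with ρ = 0.02 around
  class-specific means (background 0.80, islands 0.02, the planted
  trajectories for each class). 30× was sized by a power
  calculation: the weakest link is the 4 hpf technical-pair
  intersection test, whose per-CpG power at α = 10⁻³ for a 0.3-vs-0.8
  contrast is ≈ 0.23 at 15× (region recovery ≈ 10%) but ≈ 0.51 at 30×
  (region recovery ≥ 99% at 5 bp CpG spacing). Sperm carries the
  early-embryonic state over planted regions (the embryonic methylome
  is paternally inherited) while oocyte, brain and liver carry the
  late/differentiated state and methylated island promoters — this is
  what makes oocyte cluster with adult soma and sperm with embryos in
  the 10 kb-bin PCA.
* **Expression**: background gene means are log-normal
  (meanlog log 100, sdlog 1), counts negative binomial at dispersion
  0.1. Consistent markers are 8× PGC-enriched at every stage;
  regulators 6–10× in the stages of one of five archetypes (up-early,
  up-mid, up-late, early-sustained, late-sustained — none spans all
  four stages, keeping the marker and regulator truths distinct). The
  6–10× range follows from the gate arithmetic: with two replicates at
  dispersion 0.1 the log2FC estimate has sd ≈ 0.42, so a planted effect
  must sit ≥ 2 sd above the 1.5 threshold to be recoverable at the 90%
  level; 4× (true log2FC 2.0 less a library-composition shift) does
  not. Planted genes draw moderate baselines (meanlog log 50,
  sdlog 0.5) so that a few dozen strongly enriched genes do not distort
  library composition — with equal sampling depth, CPM fold changes are
  intrinsically attenuated by the extra PGC library mass, which is also
  why estimated marker log2FC sits slightly below log2 8 = 3.
* **PSI**: 300 background events plus 30 planted (alternating tissue
  and stage offsets of 20–40 PSI units), replicate noise sd 3, planted
  bases mid-scale (45–55) so offsets cannot clip at 0/100. Background
  cells fall below `VLOW` at rate 0.05; planted events are always
  covered — truth is recoverable by construction, mirroring the
  repeat-placement rule.

What the generator does *not* emulate: bisulfite conversion error,
strand-resolved calls, SNP/genotype effects, read-level artefacts,
chromosome-scale covariates (replication timing, compartments), or
realistic island sparsity — in a 5 Mb miniature genome the 300 islands
hold ≈ 25% of all CpGs, an order of magnitude more than in a real
vertebrate genome, so the single-CpG methylation histogram's
unmethylated mode is inflated relative to published genome-wide
histograms (the methylated mode still sits at the 0.80 baseline).
Passing recovery tests therefore demonstrates correctness of the rules
and adequate power at these effect sizes, not performance on real data.

# Numerical choices and degenerate inputs

* Dispersion floors: per-CpG ρ ≥ 10⁻³; DE dispersion ≥ 0 with
  moderation; zero variance with a nonzero difference yields p = 0
  (infinite z), zero difference yields p = 1.
* Fisher and exact-test two-sidedness uses the point-probability rule
  with a 1 + 10⁻⁷ tolerance factor against floating-point ties — the
  convention of the standard statistical environments.
* Degenerate Fisher margins return p = 1 with a flag; constant
  promoter trajectories have undefined correlation and never pass;
  zero-variance t-test inputs return t = 0, p = 1.
* PCA restricts to bins valid in every sample (no imputation), centres
  columns, and factors by SVD; an all-identical input returns a
  degenerate flag rather than NaNs.
* All placement and sampling loops are seeded; identical configuration
  and seed reproduce byte-identical fixture bundles and pipeline
  outputs (checksums in the run manifest).

# Problem sizes used by the test suite

Unit tests run on a 1 Mb miniature configuration (120 genes, reduced
planted counts). The acceptance suite sweeps ten seeds of the full
default design for recovery, uses 500 random instances for the
brute-force DMR-path equivalence, enumerates every 2×2 table with
N ≤ 30 for the Fisher oracle, and 10,000-unit null simulations for
calibration; null-methylome DMR checks use twenty 1 Mb seeds. These
sizes were chosen to give the recovery and calibration estimates
stable first decimals.

# Known limitations

* The per-replicate 4 hpf gate (< 0.025) is tight relative to the
  planted island mean (0.01) under beta-binomial noise: for the
  smallest (200 bp) islands a replicate exceeds the gate in ≈ 1% of
  draws, so a 300-target sweep misses ≈ 1 planted promoter on average.
  This is a property of the simulated noise model, reported as-is.
* The Wald per-CpG test should not be pushed far into its tail
  (see above); the DMC threshold is a stitching device, not an
  inferential claim.
* The DE test conditions on the pooled total with a balanced-split
  null after library-size adjustment; strongly unbalanced designs
  (replicate counts differing between groups) are outside its intended
  regime.
* With two replicates, per-gene dispersion is barely estimable; the
  moderated estimate leans heavily on the common value, so a handful of
  genuinely high-dispersion genes will be anti-conservatively tested.
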