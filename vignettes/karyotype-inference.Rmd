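---
title: "Purity-aware karyotype inference from tumor/normal sequencing summaries"
author: "lohscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware karyotype inference from tumor/normal sequencing summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`lohscape` infers chromosome-level tumor karyotypes — integer copy number
(CN) and loss of heterozygosity (LoH) per autosome — from three per-sample
summaries produced by any standard alignment pipeline: read counts in fixed
genome tiles, allelic read depths at SNP positions, and tumor/normal
variant tables. Everything downstream of alignment and variant calling is
in scope; read processing, variant-calling engines, and external CN tools
are not.

The central object is the purity mixture. A sequenced tumor is a mixture of
tumor cells at fraction $\rho$ and diploid stroma at $1-\rho$. For a locus
at integer CN $c$ in tumor cells, $a$ of whose copies carry the ALT allele
of a germline heterozygous site,

$$
b(\rho, c, a) = \frac{\rho a + (1-\rho)}{\rho c + 2(1-\rho)},
\qquad
r(\rho, c) = \log_2\!\frac{\rho c + 2(1-\rho)}{2}.
$$

$b$ is the expected tumor B-allele frequency (BAF) and $r$ the expected
tumor/normal log2 depth ratio. Both are exposed (`expected_baf()`,
`expected_log_ratio()`) and drive simulation and inference symmetrically:
the generator samples data from the mixture, the caller inverts it.

Because the retained parental allele is unknown, LoH evidence uses the
mirrored BAF deviation $d = |b_T - 1/2|$ rather than $b_T$ itself. Under
one-copy loss $d \to 1/(2-\rho) - 1/2$; under copy-neutral LoH
$d \to \rho/2$, which is always larger, so a threshold calibrated on the
one-copy case also captures copy-neutral events.

Purity is a per-tumor input (default 0.5). Joint purity/ploidy estimation
is deliberately out of scope; the package consumes a supplied or assumed
$\rho$, as upstream callers commonly do.

# Stage-by-stage procedure and parameters

**Germline heterozygote detection.** A site is heterozygous when its
germline ALT fraction lies strictly within (0.4, 0.6), its depth is at
least `min_depth` (50, mirroring the variant-filter depth floor), and the
balanced-allele hypothesis is compatible with the counts at 95%
confidence. The stated compatibility rule — "probability at least 0.95 of
the reads being drawn from a balanced population" — is ambiguous as a
statistic. Read literally as "p-value ≥ 0.95" it would reject most true
heterozygotes (only counts at the exact binomial mode reach p near 1), so
the default reading is: the two-sided exact binomial p-value at
$p_0 = 1/2$ is at least $1 - 0.95 = 0.05$, i.e. balance is *not rejected*
at the 95% level. Both readings are available (`mode = "not_rejected"` /
`"literal"`), and the confidence level is a parameter.

**Log-ratio normalization.** Tumor tile counts are library-size scaled to
the normal total; the raw ratio uses a pseudocount of 0.5 so zero tiles
stay finite; tiles with normal count below 10 are masked. A robust local
regression (`stats::lowess`, span 0.3) of the raw ratio on log2 normal
coverage removes the coverage-dependent trend — the coverage covariate
plays the role a GC track would play at real-genome scale, and an optional
per-tile covariate column is detrended in a second pass. The track is then
recentered at the genome-wide median.

**Segment-level re-anchoring.** The median is only an unbiased zero while
aberrant tiles are a minority; in genomes with a third or more of their
length deleted it drifts into the flank of the diploid cluster (about 0.1
log2 units on heavily aneuploid simulations, enough to corrupt integer CN
at low purity). After segmentation the package therefore clusters segment
means (single-linkage, gap 0.1) and shifts the bp-heaviest cluster to
zero. The anchoring assumption — the modal state is diploid — is the
standard one for read-depth CN callers and holds for all cohorts the
generator produces; genomes whose modal state is not diploid (e.g. genome
doubled) would need an external anchor.

**Outlier smoothing.** Before segmentation, single-tile spikes are shrunk
to their window median (window 5). A tile qualifies only if it is more
than `z_cap` (3) noise SDs both from the window median and from *every*
other value in its window; the second clause preserves genuine short
segments, whose tiles have same-level neighbours. Noise SD is estimated
robustly as MAD of first differences over $\sqrt 2$.

**Circular binary segmentation.** The arc $(i, j]$ within a chromosome
maximizing the two-sample $t$ statistic (in-arc vs out-of-arc; constant
variance factor dropped, as it cancels in permutation comparisons) is a
candidate split, accepted when its permutation p-value is below `alpha`
(0.01, 1000 label permutations, early-stopped once non-significance is
certain) and every resulting part has at least `min_width` (3) tiles; the
procedure recurses into the parts. Adjacent segments with means closer
than `merge_tol` (0.05 log2 units) are merged. The $O(m^2)$ arc scan and
the permutation loop are implemented in C++; permutations draw from R's
RNG, so a seed makes segmentation fully deterministic. Parameters follow
common practice for tile-level CN data and are all configurable.

**Integer CN and LoH calls.** Each segment takes the integer
$c \in 0..8$ whose $r(\rho, c)$ is nearest its mean (ties toward diploid;
the $c = 0$ ratio is floored at $10^{-6}$ to keep the pure-tumor limit
finite). A segment is LoH when its mean mirrored deviation $\bar d$
reaches $\theta(\rho) = (1/(2-\rho) - 1/2)/2$ — half the one-copy-loss
deviation — with at least `min_hets` (10) informative sites; sparser
segments inherit the pooled chromosome-level test, and chromosomes without
heterozygous sites are reported unknown and excluded from tallies rather
than silently counted. Halving the one-copy deviation balances
sensitivity (copy-neutral LoH sits well above $\theta$) against noise on
balanced segments; at $\rho = 0.5$, $\theta = 1/12$ while balanced
segments of ≥ 10 hets at depth ≥ 50 have $\bar d$ concentrated near
$\sqrt{1/(2 \cdot 50 \cdot 10)} \approx 0.03$.

**Chromosome rollup.** Dominant CN is the bp-weighted mode; whole-
chromosome LoH requires ≥ 80% of bp in LoH segments, so partial events
surface as `heterogeneous` (more than one CN state each covering ≥ 20%)
rather than inflating whole-chromosome counts. Monosomy means LoH with
dominant CN 1; the LoH tally counts LoH of any CN, so copy-neutral events
are included.

**Variant rules.** Somatic candidates pass when tumor and normal depth are
both ≥ 50, tumor ALT reads ≥ 10, germline ALT reads ≤ 2, and the site is
outside the mappability blacklist; every failing record carries its full
reason list for audit. A germline variant is *unopposed* when its germline
BAF lies in the heterozygous band, its locus is inside called LoH, and its
tumor ALT:REF ratio is ≥ 1.5; consistency with the purity-expected ratio
$1/(1-\rho)$ is reported as a flag, not enforced, since segmental CN can
legitimately alter the expectation. Biallelic gene inactivation combines a
passing somatic variant with LoH over the locus.

**Cohort grouping.** High-LoH tumors (≥ 8 LoH chromosomes) vote on the
recurrent set (membership ≥ 80% of high-LoH tumors); tumors are then
classified: no somatic MEN1 variant → Group 3; MEN1-mutant with
chromosome 11 LoH and LoH over ≥ 80% of the recurrent set's members →
Group 1; remaining MEN1-mutant tumors → Group 2 (those without chromosome
11 LoH are flagged anomalous). The recurrent set is discovered, not
hard-coded — the canonical ten-chromosome fixture is available via
`recurrent_loh_set()` for comparisons — and the 80% overlap tolerates
noisy dropout of one or two members. Clinical association uses an exact
conditional 2×k test (k ≤ 3) with the probability-mass two-sided
convention, computed by direct hypergeometric enumeration; group
membership enters as Group 1 vs rest, the contrast the grouping motivates.

**Dosage analysis.** Expression matrices are batch-centered (per gene,
within each preservation batch) and optionally Z-scored (sample SD,
zero-variance genes flagged at Z = 0). Genes map to chromosomes and
segments by midpoint. Per tumor, the Pearson correlation between dominant
CN and mean chromosome expression quantifies the dosage effect; euploid
tumors have no defined correlation and are excluded from histograms
rather than entered as zero. Loss-vs-intact expression of a chromosome is
compared by two-sided Mann–Whitney U (exact when the smaller group has
≤ 8 tumors and no ties, normal approximation with tie correction
otherwise). A minimum-expression mask option covers the open choice of
all-genes vs expressed-genes aggregation.

# The synthetic cohort generator

The generator emulates the observable summaries of a 39-tumor study
(10 + 16 + 13 across the three groups) on a desk-scale genome: 22
autosomes of 3 Mb tiled at 3 kb (1000 tiles each), 200 SNP positions and
50 genes per chromosome. All coordinates are genome-model-relative, so
real hg19-scale tracks load into the same structures; the desk scale keeps
the full pipeline and its validation inside a test-suite budget, and the
problem sizes quoted by the tests (e.g. 200-tile CBS tracks, $10^5$
homozygous sites) were chosen on the same principle.

Defaults describe the study conditions: mean tile and SNP depth 150×,
purity uniform on 0.4–0.8 (the upstream caller's convention of fixing
$\rho = 0.5$ motivates the default purity input of the *inference*;
the real cohort's purity distribution is unpublished, so the generator
exposes purity as a free range), negative-binomial tile counts (size 50)
and beta-binomial allele counts (precision 200) with Poisson/binomial as
large-parameter limits, 60% of SNPs heterozygous, 20% of Group 1 LoH
chromosomes copy-neutral, Group 3 aneuploidy uniform on 0–6 aberrant
chromosomes. Expression follows
$\mathrm{baseline}_g + \beta (c - 2) + \mathrm{batch} + N(0, \sigma)$ with
$\beta = 0.5$ log2 units per copy, $\sigma = 0.3$, and a +1 offset for the
first of two alternating batches; gene baselines are drawn $N(6, 1)$ and
then centered within each chromosome, so chromosome-scale expression
differences are purely dosage-driven (the noiseless limit of the
per-tumor CN–expression correlation is then exactly 1, which the tests
exploit). Injected variants include a MEN1 driver on chromosome 11 with
read counts consistent with the retained-allele frequency, unopposed and
opposed germline heterozygotes, and four classes of below-threshold
artifacts (low depth, low tumor support, germline-supported, blacklisted)
that must fail the filters for their intended reasons. Clinical labels
carry a group-linked severity gradient (metastasis probability 0.4 / 0.02
/ 0.15 by group) so association tests have signal to find.

What the generator does *not* emulate: read-level data, sequence content
and GC bias (beyond the optional covariate hook), mapping artifacts beyond
the blacklist, subclonal heterogeneity, replicate-level batch structure,
and sex chromosomes. Passing tests therefore demonstrate correctness of
the inference under the stated generative model — mixture means, NB/BB
noise, additive batch offsets — not robustness to every failure mode of
real libraries.

# Numerical choices and degenerate inputs

* Pseudocount 0.5 before log2; normal-count floor 10 for masking; ≥ 100
  unmasked tiles required for a stable fit.
* Exact binomial p-values use a relative tolerance of $10^{-7}$ when
  summing point masses, avoiding float-noise tie-breaks; the same guard
  applies to the 2×k enumeration.
* CN ties break toward diploid; the $c=0$ expected ratio is floored.
* Chromosomes with unknown LoH propagate `NA` and are counted separately
  (`n_unknown`), never as negatives.
* Degenerate clinical tables (a single group or a single outcome level)
  skip the exact test with a warning instead of fabricating a p-value.
* Seeds: every stochastic stage (simulation, CBS permutations) draws from
  R's RNG under an explicit seed; the cohort generator derives
  per-stage streams from its master seed so stages can be re-run
  independently yet reproducibly.

# Known limitations

* Purity is consumed, not estimated; a badly wrong $\rho$ shifts integer
  CN assignments (the spacing between expected ratios shrinks with
  $\rho$, so calls at $\rho < 0.2$ are unreliable by construction).
* The modal-cluster re-anchoring assumes a diploid majority; whole-genome
  doubled tumors would be mis-anchored.
* Mirrored-BAF LoH calling cannot distinguish which parental allele was
  retained, and phasing is out of scope.
* Multi-allelic variant records use the first ALT only.
* The three-group classification is only as good as the mined recurrent
  set; cohorts without any high-LoH tumor fall back to an empty set, in
  which case no tumor can satisfy the Group 1 rule.
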