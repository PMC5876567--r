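---
title: "Methods: homozygosity, segment sharing and case-control association in ibdscan"
author: "ibdscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygosity, segment sharing and case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ibdscan)
```

## Scope and data model

`ibdscan` analyses biallelic SNP-array genotypes of a small case/control
cohort — the motivating setting is a congenital-defect study in a commercial
swine herd, where a few dozen affected piglets are matched to healthy
penmates and genotyped on a ~60k chip. The central container,
`GenotypeData`, extends `RangedSummarizedExperiment`: the `"calls"` assay
holds allele-1 copy counts (0/1/2, `NA` missing) with markers as rows
(positions in `rowRanges`, 1-based bp, intervals closed on both ends) and
the sample sheet in `colData`. Markers are always stored sorted by
(chromosome, bp) with `"X"` after `"18"`, and after quality control
allele 1 is the minor allele, so every downstream count is a minor-allele
count. Alleles are treated as opaque labels; the package never flips
array-reporting strands.

## Quality control

`filterMarkers()` removes samples first (missingness > 10% by default),
then markers, mirroring common array-QC convention. Call-rate and MAF
failures are tabulated *jointly* — failed call rate only, failed MAF only,
failed both — because published study summaries report exactly those three
categories and a partition identity makes the bookkeeping auditable:
`markers_out = markers_in − callrate_only − maf_only − both − hwe`. The
identity is enforced by the `QcReport` validity method, and the report
carries both the pre- and post-HWE panel sizes since published counts
sometimes quote the panel before the Hardy–Weinberg removals.

The HWE test is the exact two-sided test conditional on the observed
allele counts (the Levene–Haldane distribution over heterozygote counts),
without a mid-p adjustment — the default behaviour of the standard
GWAS tooling this pipeline mirrors. The p-value sums all heterozygote
configurations no more probable than the observed one; probabilities are
evaluated by the usual two-directional recurrence, which is numerically
stable at array-scale counts. It is applied to markers surviving the
call-rate/MAF screens, on all remaining samples (cases and controls
together), at the chip-scale threshold 9.5e-7.

MAF is computed on non-missing calls only. The heterozygosity screen
(`sampleHetCheck`) computes F = 1 − observed/expected heterozygosity per
sample and flags F more than 3 SD *below* the cohort mean — heterozygosity
excess, the signature of cross-contamination.

LD pruning (`ldPrune`) is the greedy windowed procedure: windows of 50
SNPs stepped by 5 along each autosome; while any retained pair in the
window has r² ≥ 0.2 (squared Pearson correlation of allele counts over
pairwise-complete samples), the member with the lower MAF is dropped (tie:
the later bp). Window and step are not dictated by the motivating study,
so the conventional 50/5 defaults are used and exposed. A pair whose r² is
undefined (zero variance among complete cases) is treated as offending, so
one member is pruned rather than silently kept. Pruning is idempotent, and
sex-chromosome markers never enter the pruned panel because recombination
on X differs from the autosomes.

## Relatedness and background outliers

The pruned autosomal panel feeds three views of cohort structure. The IBS
distance 1 − (mean IBS)/2 over pairwise-complete markers feeds classical
(Torgerson) MDS via `stats::cmdscale`; each dimension's sign is fixed
(largest-magnitude loading positive) so projections are reproducible.
Genetic-background outliers are usually removed by eye in published
analyses; for reproducibility `flagBackgroundOutliers()` replaces that
judgement with a deterministic rule — distance from the per-dimension
median centre of dimensions 1–2 greater than median + 3 × MAD — plus an
explicit override list for analysts who want the by-eye decision anyway.

`ibdPiHat()` is the method-of-moments IBD estimator: expected IBS-state
probabilities under IBD states 0/1/2 are derived from panel allele
frequencies, averaged over each pair's complete polymorphic markers, and
the state proportions Z0, Z1, Z2 are solved sequentially, bounded to
[0, 1] and renormalised; PI_HAT = Z1/2 + Z2. Using per-panel frequencies
in a cohort of ~50 related animals biases the estimator mildly (order
1/(2n)); this is accepted and documented rather than corrected, matching
the scale of the motivating study.

## Runs of homozygosity and FROH

`detectRoh()` is a sliding-window scan per sample over the autosomes: a
window of 50 consecutive SNPs is homozygous if it contains at most one
heterozygous and one missing call; each SNP's hit rate is the fraction of
overlapping windows that are homozygous; SNPs with hit rate ≥ 0.05 are
eligible; maximal runs of eligible SNPs are reported if they contain
≥ 100 SNPs and span ≥ 1,000 kb. Two interpretation choices are fixed
deliberately: the heterozygote/missing tolerance applies at the *window*
level only (no additional per-segment allowance), and no SNP-density or
maximum-gap constraints are imposed, since the mirrored protocol states
none. Segment length is (end_bp − start_bp)/1000 kb; the sub-kb
difference from the closed-interval span is immaterial against the
1,000-kb threshold and keeps the arithmetic exactly testable. The
hit-rate threshold 0.05 is the scanning-tool convention, exposed in
`rohParams()`.

FROH divides a sample's summed ROH length by the genome length L. The
default L = 2,808,525 kb is the autosomal swine genome of the Sscrofa10.2
assembly; the pipeline uses the summed autosomal map span of the analysed
panel when no L is supplied, which is the correct denominator for
simulated maps. Group comparison uses the Welch two-sample t-test: the
protocol says only "standard t-test", and unequal group sizes (35 vs 18)
with possibly unequal variances make Welch the safer reading. A group
with numerically zero variance is handled with a variance floor and
flagged rather than returning NaN.

## Pairwise segment sharing and the permutation test

`detectSharedSegments()` reuses the ROH window machinery on a sample
pair: a 50-SNP window is compatible if it contains at most one
opposite-homozygote marker (IBS 0) and one marker missing in either
sample; eligibility and run extraction are identical, with the same
100-SNP / 1,000-kb segment filters, on the LD-pruned autosomal panel.
The one-IBS0-per-window tolerance mirrors the ROH heterozygote allowance
because the mirrored protocol states no separate genotyping-error budget
for sharing; it is exposed in `sharingParams()`.

The sharing statistic is evaluated per marker position of the pruned
panel: the count of case/case pairs whose segment overlaps the position
(control-involving counts are tabulated alongside as diagnostics). The
granularity is a design decision — the protocol never defines it — and
per-position counting matches how such scans are displayed, while the
multiplicity over correlated positions is controlled by a within-chromosome
max-statistic correction rather than a Bonferroni across positions.
`sharingPermutationTest()` permutes case/control labels uniformly over
samples with group sizes fixed; segments are label-free and are *not*
recomputed. Pair labels are induced by sample labels, preserving the
dependence between pairs that share a sample. Empirical p-values use the
add-one formula (1 + exceedances)/(1 + n_perm), so p = 0 is impossible
and the floor is 1/(n_perm + 1); with the reference setting of 100,000
permutations the smallest attainable p is ~1e-5. The CLI default is
10,000 permutations (desk scale); results are bit-identical for a fixed
seed. Because the statistic is a small integer count, the test is
discrete and slightly conservative at positions with little sharing;
calibration is therefore checked at positions covered by at least one
segment.

## Association and haplotypes

`allelicTest()` builds the per-marker 2×2 minor/major × case/control
allele-count table and applies the Pearson 1-df chi-square without
continuity correction. The odds ratio uses the Haldane–Anscombe +0.5
correction on all cells only when a cell is zero, so a haplotype or
allele absent from one group still reports a direction instead of an
infinite estimate. Significance follows the protocol's fixed genome-wide
screen p < 5e-5 with no further multiple-testing correction (a Bonferroni
option exists behind the pipeline threshold parameter). The genomic
inflation factor is median(chi²)/0.4549 and the QQ table uses
(rank − 0.5)/n expectations. On the X chromosome, genotypes are analysed
exactly as delivered by the array (diploid coding); the cohorts this
mirrors are castrated males genotyped on autosomal-style clusters, and no
hemizygosity model is attempted — a documented limitation.

Combined-marker effects are estimated by EM haplotype-frequency
estimation over the 2^m haplotypes of m = 2 or 3 markers (uniform
deterministic initialisation; E-step weights each individual's compatible
unordered haplotype pairs by frequency products; convergence at maximum
frequency change < 1e-8 or 1,000 iterations, the last iterate returned
flagged if unconverged; the log-likelihood is non-decreasing and asserted
so in tests). Cases and controls are fitted separately; expected
haplotype counts 2n·f feed a haplotype-vs-rest 2×2 chi-square per
haplotype plus an omnibus (h−1)-df test. Haplotypes with expected count
below 1 in both groups are reported descriptively, not tested. Treating
EM-expected counts as observed counts makes these tests mildly
anticonservative in small samples — a known property of this classic
procedure, shared with the tooling it mirrors, and the reason the package
reports the omnibus test alongside the per-haplotype ones rather than in
place of them. Whether published haplotype percentages are carrier
frequencies (animals with ≥ 1 copy) or chromosome frequencies is often
ambiguous; the report therefore carries both: EM chromosome frequencies
and posterior carrier frequencies.

Per-marker effect sizes come from single-predictor logistic regression
(IRLS, tolerance 1e-10, max 50 iterations); complete or quasi-complete
separation — inevitable when an allele is absent from one outcome class —
is detected and flagged, and no Wald p is emitted for separated fits.

## The synthetic generator: what it emulates, and what it does not

`simulatePopulation()` gene-drops founder haplotypes through a
three-generation pedigree with Haldane (no-interference) crossovers on a
1 cM/Mb map. The default herd pedigree (5 founder sires, 20 dams, 40 G1,
220 finals from 40 matings) produces exactly the structure the analysis
stages assume: partial relatedness across the cohort (full sibs,
half-sibs and cousins, PI_HAT spanning roughly 0–0.55) and moderate
inbreeding from matings between relatives (mean realized autozygosity
near 0.03, individual values spanning roughly 0–0.1, bracketing the
FROH range reported for real commercial cohorts). A dedicated
first-cousin pedigree produces offspring with pedigree F = 1/16 for
parameter-recovery checks. Mendelian consistency of every transmitted
haplotype is recorded (founder-origin matrices) and asserted in tests.

The risk locus is implanted on founder chromosomes: with probability
0.285 a founder haplotype carries the risk allele string across a 5-Mb
span; at the two focal markers the background allele-1 frequency is set
to 0.75, so the protective pattern (allele 1, allele 2) segregates at
~13% of chromosomes while the risk pattern (allele 2, allele 2) reaches
~32%. Penetrances are attached to *state* carriers at the focal pair —
0.64 for risk carriers, 0.21 for non-carriers, and 0 for protective
carriers. The defaults were derived analytically (before any testing)
so that a 35-case/18-control draw shows the published two-sided pattern
of a strong risk-haplotype report: risk carriers in ~83% of cases vs
~40% of controls, protective carriers in 0% of cases vs ~39% of
controls. The protective-pattern penetrance is a deliberate
generalisation of a single-penetrance-pair model: a carrier/non-carrier
dichotomy alone cannot make the alternative haplotype vanish from cases,
which is half of the two-sided pattern being emulated.

What the generator does **not** emulate: realistic swine LD decay
(background markers are independent given the pedigree), sex-specific
transmission on X (X is dropped like an autosome), genotyping error
(only missingness is injected), and ascertainment by pen-matching.
Passing tests therefore demonstrate correctness of the algorithms and
calibration of the tests under pedigree-induced dependence — not
robustness to chip-specific artefacts.

A note on detection power at this design point: a carrier pattern of
~83% vs ~40% at 35/18 animals carries a 2×2 chi-square noncentrality of
about 10 — enough to localise a signal at nominal p ~ 1e-3, but far
below what a p < 5e-5 genome-wide detection demands (noncentrality ~24
for 80% power). The generator holds the published effect size rather
than inflating it, so end-to-end runs typically rank the implanted locus
highly without crossing the genome-wide threshold; the power of the
segment-sharing permutation test is instead demonstrated with explicitly
forced shared segments (`implantSharedSegment`).

## Numerical choices and problem sizes

Ties in the HWE tail sum use a 1e-9 relative tolerance; EM convergence is
1e-8 on frequencies; logistic IRLS 1e-10; MDS sign fixing as above;
permutation p-values add-one. Degenerate inputs fail loudly: an all-QC'd
panel raises an "empty panel" error rather than an empty success, a pair
with no overlapping calls names the pair, an unlabelled sample names the
contract.

Test and validation runs use deliberately desk-scale problem sizes chosen
to exercise every code path while keeping the whole suite in minutes on
one core: oracle equivalence on ≤ 500-SNP instances, calibration on
2,000–4,000-marker null panels, permutation calibration on 60 replicate
24-animal cohorts at 199 permutations, FROH recovery on a ~25k-marker
map with 40 first-cousin offspring, and end-to-end pipeline runs on
~800–5,550-marker cohorts with a few hundred permutations.

## Known limitations

Small-sample bias of the moments IBD estimator with in-panel allele
frequencies; diploid treatment of X; EM-count chi-squares are
approximate; the sharing permutation test's granularity (per pruned-panel
position) inherits the pruned panel's density, so sparse chromosomes are
evaluated coarsely; ROH calling has no density/gap constraints, so very
sparse maps can admit long gap-spanning segments — use denser maps or
raise `minSnps` accordingly.
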