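---
title: "Methods: calling and testing alternative polyadenylation from long-read 3' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and testing alternative polyadenylation from long-read 3' ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A 3'-primed long read starts at the poly(A) tail, so the 3'-terminal
aligned base of its primary alignment estimates the cleavage site of
the molecule. `longapa` works entirely from these per-read endpoints
plus a read-to-gene assignment. Two conventions run through the whole
package:

* **Coordinates** are 0-based half-open internally; GTF (1-based
  inclusive) and BED (0-based half-open) are converted at the I/O
  boundary, which confines off-by-one risk to two functions.
* **Orientation** is transcriptional. The 3' end of a read is the last
  aligned base for genes on `+` and the first aligned base for genes
  on `-` — taken from the *assigned gene's* strand, not the alignment
  flag, because cDNA reads may align antisense while direct RNA reads
  are sense-stranded. Soft-clipped bases (adapter, tail) are never
  genomic and are excluded. Reads whose ends fall outside the
  annotated gene span are retained: they may define unannotated
  downstream sites, and dropping them would bias against 3'UTR
  extension.

## PAS calling

Cleavage is locally heterogeneous: reads from one site scatter over a
short window. Per gene, ends pooled over *all* samples are clustered
greedily: the coordinate with the highest read depth becomes a peak
and absorbs every unassigned coordinate within the window (20 nt
default), repeating until all ends are assigned. Depth ties break to
the transcription-proximal coordinate, then the lower genomic
coordinate, making the procedure fully deterministic; a mirrored
genome therefore yields mirrored calls exactly (this is asserted in
the tests). Pooling before clustering gives a single catalog shared by
all samples — a prerequisite for comparing usage across conditions.

A peak's **overall PAU** is its cluster depth divided by the gene's
pooled read count. Peaks below `min_overall_pau` (default 0.01) are
dropped, and overall PAU is deliberately *not* renormalised
afterwards: it remains interpretable as "fraction of all observed
molecules of this gene". Retained PASs are ranked proximal to distal.

Classification against an optional reference PAS set is
strand-specific: distance 0 with a compatible host-gene label is
`match`; within 20 nt (absolute distance) is `proximity`, with the
signed transcription-oriented distance recorded; otherwise `novel`. A
zero-distance site labelled with a *different* gene is reported as
`proximity`, reserving `match` for same-gene concordance. Because
public PAS databases differ in how interval ends are oriented, the
loader takes the strand-wise 3' base of each BED interval as the site
coordinate — a documented convention, not something the databases
standardise.

## Internal priming

Oligo-dT priming on genomically encoded A-stretches manufactures false
3' ends. The rule here is deliberately literal: a peak is flagged when
the 10-nt sense-strand window immediately 5' **or** 3' of the peak
(peak base excluded) contains strictly more than 6 adenosines — total,
not consecutive; a 6-A flank is clean. Flagged PASs stay in the
catalog (users should see them) but are excluded from the PAS-level
test by default; the gene-level test keeps them unless asked,
because removing reads changes the gene's 3'-end distribution itself.

## Quantification

Counting reassigns each read to the nearest retained PAS within the
calling window (equidistant ties to the proximal site); unassignable
reads are tallied per gene. PAU is the per-sample compositional
fraction over the gene's retained PASs, defined only when the
gene-sample depth reaches `min_gene_reads` (default 10; the motif
group analysis uses a stricter per-sample floor of 20, both surfaced
as parameters because no single depth rule suits every analysis).
ΔPAU between conditions is the difference of means over *eligible*
samples — not pooled counts — so replicate variability stays visible;
per eligible gene-sample the PAU simplex closes to 1 within 1e-9
(asserted across whole runs).

## Gene-level statistic

For gene-level lengthening/shortening the two conditions' reads are
pooled (the statistic is thus defined even without replicates) and
their transcription-oriented 3'-end empirical CDFs compared at every
distinct position:

D⁺ = max(F̂_a − F̂_b), D⁻ = max(F̂_b − F̂_a),
APA change = D⁺ if D⁺ ≥ D⁻ else −D⁻.

Positive values mean condition b's ends are stochastically larger —
distal shift, 3'UTR lengthening. The p-value is the asymptotic
Kolmogorov survival function at sqrt(n_eff)·D with
n_eff = n_a·n_b/(n_a + n_b), no small-sample or tie correction. Read
positions are a discrete lattice with heavy ties, which makes this
p-value conservative: in the package's own null simulations (the
acceptance script reports them) the empirical type-I error at p<0.05
sits around 0.02–0.04, versus ~0.04–0.05 for the identical machinery
on continuous data. We accept this conservatism rather than add a tie
correction: it only costs a little sensitivity and never inflates
false positives. By default only reads attributable to a retained PAS
enter the statistic (consistent with the PAU definition); `all_reads =
TRUE` lifts that. Genes need two retained PASs and `min_ks_reads`
(default 10) pooled reads per condition. BH adjustment is applied
within the gene-level family, and directions are called at q < alpha
(0.05) and |APA change| > tau (0.1). Tested genes are labelled
`last_exon_tandem` when every retained PAS lies in the union of
per-transcript last exons (or downstream of the gene span — run-off
sites are tandem usage too) and `mixed` otherwise.

## PAS-level statistic

The per-PAS test keeps the structure of the DEXSeq exon-usage test at
desk scale: for each PAS, the two-column counts (this site vs rest of
gene, per sample) are modelled as negative binomial; the null GLM has
sample and column effects (sample effects condition on total gene
output), the alternative adds the condition-by-column interaction,
and twice the log-likelihood difference is referred to χ²(1). This is
an approximation to DEXSeq — no Cox–Reid adjusted shrinkage, no joint
exon model — and is documented as such.

Dispersion is method-of-moments, computed *conditionally on the
gene-sample totals*: the expected count is the total times the
condition-mean usage, so library-size variation cannot masquerade as
usage dispersion. The raw estimate (df-corrected, floored at 1e-8,
capped at 10) is shrunk 50/50 on the log-mean trend fitted by lowess
across all PASs — the floor keeps Poisson-like data Poisson, the trend
stabilises the n=6 designs the method is meant for. The usage fold
change is the ratio of condition-mean PAUs guarded by a pseudo-usage
of 0.5/(mean gene total), and significance requires both q < 0.05 and
fold change beyond 1.5 (on the usage scale; a normalised-count scale
is a plausible alternative reading, and the threshold parameter
applies unchanged if users precompute such values). The test requires
two replicates per condition and refuses to run otherwise, pointing
users to the gene-level statistic.

Across genes, the gene-level APA change should anti-correlate with the
proximal PAS's ΔPAU and correlate with the distal one's;
`proximal_distal_correlation()` computes both Pearson coefficients as
a structural sanity check of any run.

## Sequence features

Windows of −100..+100 nt around sites are extracted transcription-
oriented and RNA-converted. Position 0 is the cleavage/peak base;
motif positions refer to match *starts*. Composition profiles exclude
N bases column-wise; incidence counts every overlapping match, and
windowed aggregates use any-match semantics (whether overlapping
occurrences should count once or many times is not standardised; for
presence fractions the two coincide). Plot smoothing is a centered
moving average (window 5). PAU-enrichment site groups use the
fraction scale with δ = 0.1 (equivalent to 10 percentage points).

## The synthetic-data generator

The generator emulates the features the statistics rely on, with every
truth recorded: two-exon genes on both strands (a fraction with an
intronic proximal PAS, giving mixed-type genes), 2–5 true PASs at
least 40 nt apart so the 20-nt window cannot merge them, AAUAAA
planted with match start 20–30 nt upstream of every site, per-gene
usage simplexes with planted lengthening/shortening shifts of
`delta_pau` moved between the proximal and distal site, NB-distributed
per-gene-sample depth (dispersion 0.1), and discretized-normal 3'-end
jitter rejection-truncated at ±15 nt. Defaults are fixed at
depth_mean = 67 reads/gene/sample — three replicates give the ~200
pooled reads per condition that the recovery analyses are defined on —
and jitter_sd = 5 nt, a typical direct-RNA cleavage spread. Clean
sites' 10-nt flanks are repaired to at most 5 sense adenosines, so no
true site can trip the artifact rule; decoy sites get an 8-A upstream
flank and emit reads at 8% of gene depth *without jitter*, because
internal-priming ends are templated by the genomic A-tract rather than
produced by heterogeneous cleavage. Truncating jitter at ±15 nt keeps
each true cluster inside its own calling window, deliberately
separating statistical behaviour from peak-merging behaviour.

What the generator does **not** emulate — alignment error, antisense
artifacts, expression-level confounding, overlapping genes, multi-PAS
microheterogeneity below 40 nt — bounds what green tests prove: they
validate the statistics and the bookkeeping, not robustness to every
property of real libraries.

## Problem sizes and numerical choices

The packaged analyses use 500-gene fixtures with 3 vs 3 replicates for
null and recovery studies, 1,000-instance oracle sweeps for the
clustering and KS equivalence checks, and 40–60-gene fixtures for
mirroring and artifact studies — sizes chosen so the whole suite runs
comfortably on a laptop while leaving binomial noise on rate estimates
near ±0.01. Degenerate inputs are defined, not special-cased: empty
end sets cluster to nothing, empty references make everything novel,
genes with one retained PAS are excluded from both tests, zero-depth
gene-samples are ineligible rather than zero, and flank windows
clipped at chromosome ends are evaluated on the available bases with
the clip lengths reported.

## Known limitations

* The KS p-value is conservative on tied data (above); very shallow
  genes lose power accordingly.
* The PAS-level test approximates DEXSeq; exact agreement with DEXSeq
  output is out of scope, as are >2-condition designs and covariates.
* PAS calling is purely depth-driven — no poly(A)-signal-guided peak
  correction and no model-based deconvolution of closely spaced sites.
* The BAM adapter consumes unique gene assignments only; fusion and
  chimeric reads are not handled.
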