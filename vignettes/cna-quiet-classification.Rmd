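---
title: "Classifying CNA-quiet tumors: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CNA-quiet tumors: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most HPV-negative head and neck squamous cell carcinomas carry many
somatic copy-number alterations (CNAs), but a clinically distinct
minority — "CNA-quiet" tumors — carry few or none. Identifying them from
bulk sequencing is confounded by stromal contamination: the tumor-cell
fraction (purity) dilutes the copy-number signal toward diploid, so
low-purity CNA-high tumors masquerade as quiet. `cnaquiet` implements a
quantitative classification that corrects for this: purity/ploidy-aware
recalculation of the fraction genome altered (FGA), panel-of-normals
segment calling for low-coverage WGS (lcWGS), a platform-calibrated
decision rule, an MLPA pre-screen, variant-based purity and power QC, and
the cohort statistics used to characterize the resulting subclasses.

## The mixture model

Every copy-number quantity in the package derives from one mixture
identity. A locus with `cn` copies in a tumor of purity $p$ and average
ploidy $\psi$, mixed with diploid stroma, is observed (on the linear
relative scale, 1 = sample average) at

$$v(cn) = \frac{p\,cn + 2(1-p)}{p\,\psi + 2(1-p)},$$

inverted by `absolute_cn()`. Three consequences shape the pipeline:

* `v` is affine and increasing in `cn`; **lower purity flattens the
  observable spread**, which is why uncorrected FGA collapses in
  low-purity tumors;
* a value of 1 always maps back to the ploidy, so the fit is anchored by
  the sample normalization (profiles are median-centered to 1);
* the expected VAF of a variant on $m$ of $C$ copies is
  $p\,m/(p\,C + 2(1-p))$ (plus $m_s(1-p)$ in the numerator for a germline
  variant on $m_s$ stromal alleles), linking read counts to the same
  purity.

## Purity and ploidy fitting, and what it cannot do alone

`fit_grid()` scores every `(purity, ploidy)` grid point (defaults:
purity 0.05–1.00 step 0.01; ploidy 1.5–5.5 step 0.05, wide enough for
genome-doubled tumors) by the length-weighted RMS distance of implied
absolute copy numbers to their nearest non-negative integers. Ties break
toward higher purity, then lower ploidy — the parsimonious reading of a
diluted profile.

Read-depth ratios alone, however, cannot identify the fit in general: a
diploid tumor at purity $p$ has an *exact* triploid re-interpretation at
purity $2p/(2-p)$ with the same integer-lattice spacing and the same
noise scale, and ploidy-4 profiles always admit a diploid reading at
$p/(p+1)$. This is a property of the data, not of the algorithm; it is
the reason tumor copy-number studies combine a read-depth fit with an
orthogonal estimate (allele-frequency-based tools, variant copies, or
manual review). The package follows the same logic: `consensus_fit()`
re-ranks grid candidates by `error × (1 + d)` where `d` is the distance
to an externally supplied fit,

$$d = \sqrt{(p_{grid}-p_{ext})^2 + (\psi_{grid}-\psi_{ext})^2/5},$$

the division by 5 bringing the ploidy difference into balance with the
purity difference. The multiplicative `1 + d` form is monotone,
dimensionless, and leaves the ranking untouched when a candidate agrees
exactly with the external estimate. For copy-number-flat profiles
(`fit_grid` flags them degenerate) purity comes from somatic VAFs
instead: `purity_from_vaf()` uses the 90th-percentile VAF under the
heterozygous single-copy diploid model (`purity = 2·VAF`), robust to
subclonal variants without being inflated by the noisiest site.

In simulations, grid fitting alone recovers the generating purity only
in the identifiable regime (diploid truths with purity above 2/3, where
the alternative lattice would need purity above 1); with an external
estimate carrying realistic error (SD 0.03 purity, 0.1 ploidy), consensus
fitting recovers purity with median absolute error below 0.01 across
purities 0.3–0.9 and ploidies 2–4.

## Segmentation and calling

lcWGS profiles are 500-kb binned read ratios. Background correction
(`subtract_background()`) removes the projection onto the two leading
principal components of a panel of FFPE-derived normal controls —
recurrent platform/fixation waves — then re-centers to median 1. The
projection coefficients are fitted robustly (bins within 3 MADs of the
center only): a strong alteration such as a homozygous deletion in a
high-purity tumor would otherwise leak into the projection and smear
component-shaped artifacts genome-wide.

`segment_bins()` is a deterministic change-point scan in the spirit of
circular binary segmentation: each chromosome is searched for the
interior window whose mean deviates most from its complement (two-sample
z statistic with pooled SD, prefix-sum implementation), the window is
accepted above a threshold (default 5) if every resulting piece keeps at
least `min_size` bins (default 3), and pieces are scanned recursively.
Testing windows rather than single split points matters: with several
alternating gains and losses on one chromosome, every single split point
has nearly equal side means and the naive binary split finds nothing.

`call_segments_pon()` calls a segment when it deviates from the panel
both practically and statistically: absolute deviation above
`abs_cutoff = 0.02` *and* a two-sided z-test at `alpha = 0.001` with
standard error `pooled panel SD / sqrt(n_bins)`. The conservative alpha
keeps flat profiles sparsely called, which the quiet/other decision
depends on.

## From copy numbers to the classification

With a fit in hand, segment values become absolute copy numbers; the
modal copy number is the integer state covering the greatest genomic
length (ties toward the ploidy); a segment is *altered* when its copy
number differs from the modal state by strictly more than 0.5 copies
(the boundary case is not altered). FGA is the altered (or, for lcWGS,
called) genomic length divided by the total.

The decision rule: **CNA-quiet iff FGA < 0.20 and fewer than the
platform cutoff of called segments** — 20 on SNP arrays, 6 on lcWGS.
The lcWGS cutoff is the SNP-array cutoff rescaled by the ratio of mean
called-segment counts between platforms (48.3 vs 13.4, a factor 3.6;
`calibrate_segment_cutoff(48.3, 13.4, 20)` = 6, half-up rounding). The
segment-count condition exists because a CNA-high tumor with many small
segments can have a low FGA; the FGA condition exists because a single
whole-arm event can dominate length while the genome stays otherwise
quiet. An opt-in variant of the rule (`casp8_override = TRUE`) also
admits CASP8-mutated tumors to the quiet class regardless of profile;
the main classification is defined without it. `fga_category()` bins FGA
at 0.08 / 0.20 / 0.46; the edges are taken as [0, 0.08), [0.08, 0.20),
[0.20, 0.46], (0.46, 1] — the category boundary coincides with the 0.20
classification cutoff, and 0.46 belongs to the third category. That the
narrow band [0.19, 0.20) belongs to the second category is this
package's convention.

## MLPA pre-screen

The probe set covers ten regions recurrently gained or lost in
HPV-negative head and neck cancer (36 classification probes; 13
reference probes in rarely-changed regions for normalization). Ratios
are normalized within-sample by the geometric mean of the reference
probes and between samples by the median of healthy controls. A probe is
aberrant strictly outside [0.7, 1.3] (boundaries count as normal); a
region scores as changed with at least 2 same-direction aberrant probes
(3 for the probe-richer 3q26 and 11q13), plus one extra whenever any
probe points the opposite way — applied symmetrically to gains and
losses, which is this package's reading of an asymmetrically worded
rule. More than two changed regions makes the sample *definitive other*
(no genome-wide follow-up needed); two or fewer leaves it a *quiet
candidate* for lcWGS, since changes may lie outside the probed regions
or purity may be too low for probes to exit the normal range (as purity
falls, all probe ratios contract toward 1 — the pre-screen loses
sensitivity but not positive predictive value).

## Variants and power

`filter_variants()` applies the somatic retention rules: both callers,
VAF ≥ 0.02, ≥ 3 supporting reads; germline removal (population allele
frequency ≥ 0.01, common in dbSNP, or more than 5 panel-of-normals hits)
with a rescue for variants previously confirmed somatic; intronic,
silent and UTR records removed except TERT promoter and TP53 5'-UTR.
`link_variant_copies()` assigns each variant the copy configuration
(somatic or germline, $m$ copies) whose expected VAF is nearest the
observation in binomial-SD units; exact ties break toward the
single-copy model ($m = 1$) and then toward somatic — the canonical
clonal interpretation.

Power gates sample QC. For segments, the expected deviation of a
single-copy event is $p/(p\psi + 2(1-p))$ and power is the normal-model
probability of exceeding the calling threshold
(`max(abs_cutoff, z_crit · SE)`); the minimum of gain and loss power is
reported (they coincide under the symmetric model — the minimum is kept
as the conservative convention). For variants, the read threshold is the
largest of: the smallest count whose sequencing-error tail probability
falls below `alpha_noise = 1e-4` (error rate default 0.001, exposed as a
parameter), the 3-read minimum, and 2% of depth; power is the binomial
upper tail at the expected VAF. A sample passes QC when purity ≥ 0.10
and more than 80% of the genome has over 80% single-copy calling power.

## The synthetic cohort: what it does and does not emulate

`simulate_*()` generators produce every input the pipeline consumes,
deterministically per seed: integer-copy clones diluted by stroma with
multiplicative lognormal bin noise (SD 0.05) and an additive FFPE-like
background built from two fixed genome-wide sinusoids (per-sample
coefficients, SD 0.02) that the panel's PCA should capture; MLPA ratios
from the same mixture with probe noise SD 0.05; binomial variant read
counts at purity-determined VAFs, with decoy records the filter must
remove; and two-arm cohorts with group-dependent covariate frequencies
and exponential survival (quiet-vs-other hazard ratio 0.44 around a
baseline of 50% five-year survival, uniform censoring on 0–120 months).
Event placement mildly favors gains and losses on chromosomes 3 and 8,
echoing the characteristic alteration pattern of this tumor type.

Simulated studies use two genome scales: the hg19 autosome layout with
12–15 arm-scale events (20–80 Mb) for purity-recovery and FGA-rescue
studies (50–100 samples, a few minutes in total), and a 3 × 50 Mb toy
layout with 2–10 Mb events for fast end-to-end classification checks
(quiet = 0–3 events, other = 8–12 events, 100 samples). These generators
emulate the *statistical* structure the method assumes — mixture
dilution, shared background, binomial sampling. They do not emulate
GC/mappability bias, replication-timing waves, subclonal heterogeneity,
FFPE artifact spectra, segmentation-scale platform differences, or
allele-specific signal; passing tests therefore demonstrate internal
correctness of the machinery under its stated model, not performance on
real specimens.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive everywhere (SEG convention), in
  files and in memory; segment length is `end − start + 1`.
* Segment values are handled on the linear scale internally; log2 input
  is converted at the file boundary (`value_scale = "log2"`).
* Sex chromosomes are excluded at read time by default (retainable by
  flag), matching copy-number practice for mixed-sex cohorts.
* The 0.5-copy alteration rule and the [0.7, 1.3] MLPA normal range use
  strict inequalities (boundary values are not altered/aberrant).
* `chi_squared()` applies the Yates continuity correction to 2×2 tables
  by default and never to larger tables; the choice is always reported
  in the result, since published tables are not consistent about it.
* The Kaplan-Meier hazard ratio is computed from log-rank
  observed/expected events, `(O1/E1)/(O2/E2)`, not from a Cox model.
* Degenerate inputs error early and explicitly: empty profiles, zero
  marginals, empty groups, zero depth.

## Known limitations

Purity/ploidy identifiability (above) is the structural one. Others:
the z-statistic window scan has no significance calibration against
autocorrelated noise (real CBS permutes); the panel z-test treats bins
as independent; VAF-based purity assumes heterozygous single-copy
clonal variants in a diploid genome and is biased for variants on
altered segments; the variant filter's COSMIC rescue is an input flag,
not a lookup; and manual fit curation — part of the original workflow —
is out of scope, represented only by the external-estimate interface.
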