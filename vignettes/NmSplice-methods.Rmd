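---
title: "NmSplice: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NmSplice: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NmSplice)
```

# The scientific problem

Box C/D small nucleolar RNAs (snoRNAs) guide site-specific ribose
2'-O-methylation (Nm) of target RNAs, including spliceosomal snRNAs. When a
snoRNA that methylates a core spliceosome component is differentially
expressed - for example between primary tumours and lymph-node metastases -
three questions follow, each with its own assay and statistic:

1. **Which snoRNAs stand out?** A probe-level screen over multi-site tumour
   microarrays, with a hypergeometric test for class enrichment.
2. **Is the target site actually methylated, and how much?** An RNase-H
   protection qPCR assay (Nm-VAQ) quantified on the ddCt scale, and an
   orthogonal sequencing readout (RibOxi-seq) that piles read 3' ends on
   methylated positions.
3. **Does methylation loss reshape splicing, and does the association hold
   in patients?** Percent-spliced-in (PSI) statistics with a significance
   filter, intron-retention summaries, and patient-pair correlation of exon
   inclusion with snoRNA expression.

NmSplice implements each statistic as a small, tested operation, plus seeded
simulators that generate every input with its planted ground truth, so the
whole pipeline can be exercised and calibrated without any external data.

# Differential probe selection

The selection operates on linear-scale, normalised intensities in a
`ProbeExpressionExperiment` (a `SummarizedExperiment` whose columns carry a
replicate group and a site category: `baseline`, `MFP`, `AxLN`,
`AxLN-LuM`). For each AxLN triplet, three criteria are evaluated against the
pooled baseline replicates:

* **Fold change** - triplet mean over baseline mean at or beyond 1.5 (up)
  or 0.5 (down). Both boundaries are inclusive: the screen's phrasing "at
  least 50% above or below" is a closed condition, and we read it as the
  only interpretation consistent with a two-sided threshold. Probes with a
  zero baseline mean cannot form the ratio; they are flagged invalid and
  excluded rather than passed or silently dropped.
* **Range percentile** - the per-probe range (max minus min, the simplest
  spread statistic on a handful of replicates) over the baseline + triplet
  submatrix must reach the 25th percentile of all probes' ranges on the same
  submatrix. The percentile uses linear interpolation (R's default type 7).
  A constant probe (range 0) never passes when the percentile is positive,
  even in the degenerate case where so many probes are constant that the
  percentile value itself is 0 - a flat probe cannot be differential.
* **Consistency** - every triplet replicate strictly exceeds (or is
  strictly below) every baseline replicate. Any shared value breaks the
  ordering. With `strictDirection` (default) the ordering must agree with
  the fold-change direction.

A probe is *AxLN-distinct* when, additionally, the pooled MFP vs AxLN and
AxLN vs AxLN-LuM comparisons each satisfy the consistency relation with
AxLN on the same side of both. We deliberately do **not** require strict
separation between MFP and AxLN-LuM: a probe specific to AxLN is
baseline-like at both of those sites, so requiring their separation would
empty the selection. The third comparison is available behind
`requireThirdComparison` for screens that want it.

Two choices here were genuinely open. First, the two baseline quadruplicates
are pooled into one eight-sample reference rather than tested separately;
pooling is the simpler reading and makes the consistency criterion stricter
(eight values to clear rather than four). Second, boundary equality on the
fold thresholds is inclusive; the tests pin both choices so any revision is
visible.

Class enrichment uses the upper hypergeometric tail
$P(X \ge k) = \sum_{j\ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$
computed in log space via `phyper`, with fold $= (k/n)/(K/N)$. On the
profiled panel's printed composition - 1245 snoRNA probes of 10043, and 20
snoRNAs among 30 differential probes - this gives $p = 5.6\times10^{-12}$
and a 5.4-fold enrichment, which the acceptance suite recomputes. The same
tail backs the gene-set overlap statistic used for splicing results.

The display transform (`log2MeanCenter`) log2-transforms and row-centres
intensities; hierarchical clustering for figures is left to standard tools
and is not part of the tested surface.

# Nm-VAQ percent methylation

RNase H cleaves the RNA strand of an RNA/DNA duplex only when the ribose is
unmethylated, so the fraction of transcripts surviving a site-directed
RNase-H treatment measures methylation at that site. With Ct replicates
averaged per record,

$$\Delta\Delta C_T = (C_{T,\mathrm{target}}^{+H} - C_{T,\mathrm{ref}}^{+H})
 - (C_{T,\mathrm{target}}^{-H} - C_{T,\mathrm{ref}}^{-H}),
 \qquad \%\mathrm{Me} = \mathrm{clamp}(100 \cdot 2^{-\Delta\Delta C_T},\, 0,\, 100).$$

Choices and their reasons:

* **Amplification efficiency is fixed at 2** (perfect doubling). No
  efficiency correction is applied anywhere in the ddCt arithmetic; an
  efficiency-calibrated variant would need a dilution series the assay does
  not include.
* **Replicates are averaged before differencing**, not paired: technical
  qPCR replicates carry no pairing structure.
* **Estimates are clamped to [0, 100]**. Noise can push the raw estimate
  slightly past either end (a $\Delta\Delta C_T$ of $-0.1$ implies 107%);
  the clamp reports the physically meaningful value and the raw
  $\Delta\Delta C_T$ is returned alongside.
* **Incomplete cleavage biases upward.** If RNase H leaves a fraction of
  unmethylated templates uncut, the surviving fraction is
  $m + (1-m)(1-\epsilon)$ and the estimate overstates $m$. No correction is
  applied - the assay itself applies none - but the simulator exposes
  `cleavageEfficiency` so the bias can be studied.
* The reference gene is a required input, never defaulted, because assays
  normalise to different genes (GAPDH or RPLP0) per experiment.

The simulator emits three Ct replicates per record (standard technical
triplicates) with Gaussian noise per replicate, a basal target Ct of 22 and
reference Ct of 18 - ordinary mid-dynamic-range qPCR values. A surviving
fraction of zero yields an undetermined (`NA`) Ct, which the estimator
reports as below detection at 0%. Mixture fixtures at fractions
0/25/50/75/100% with zero noise recover a slope of exactly 1; with
0.1-cycle noise the mean absolute error over 200 samples stays under 5
percentage points (both recomputed by the tests and the acceptance script).

# RibOxi-seq Nm scoring

RibOxi-seq enriches RNA fragments whose 3'-terminal nucleotide is
2'-O-methylated, so methylated positions appear as 3'-end pileups.
`endCountTrackFromBed` tallies alignment 3' ends over a transcript: BED
intervals are 0-based half-open, so on the `+` strand the 3' end is the
interval end (equal to the 1-based inclusive end) and on the `-` strand the
interval start + 1. Out-of-range records are skipped and counted, never
silently dropped.

The **Nm score** at interior position $n$ is
$c'(n) / \left[(c'(n-1) + c'(n+1))/2\right]$ where $c'$ has zeros replaced
by 1. The substitution, originally a plotting convenience, is applied
before scoring here so the ratio is total - without it a methylated
position flanked by zero-count neighbours would be undefined exactly where
the signal is strongest. A flat track scores exactly 1 everywhere, and
scores are invariant to scaling the library depth wherever no substitution
fires; both properties are pinned by tests.

Site calling is conjunctive: Nm score $\ge 4$ **and** raw count $\ge 10$ by
default. The underlying assay reports detected sites without stating a
numeric rule, so these are artifact defaults, fully configurable, chosen so
that a clear pileup (an order of magnitude over background) is called while
Poisson fluctuations at moderate coverage are not. Differential comparison
between genotypes is the direction-resolved set difference of the two call
sets.

The default fixture is a 106-nt U6-like transcript with eight methylated
positions in the wild type, including position 60 (the site guided by the
snoRNA of interest), and seven in the knockout (60 absent). The other seven
positions are arbitrary defaults, spaced at least two nucleotides apart so
neighbour normalisation does not suppress adjacent sites. Background
coverage defaults to `backgroundRate = 5` with a depth multiplier of 10 -
a mean of 50 read ends per position, modest for an abundant snRNA - and a
20-fold site enrichment. Under these conditions the planted site-60 loss is
recovered in essentially every seeded replicate with no spurious
differential sites, which the acceptance suite verifies over 50 pairs.

# Splicing statistics

PSI from junction counts is effective-length-normalised:
$\mathrm{PSI} = (I/l_I) / (I/l_I + S/l_S)$, reducing to $I/(I+S)$ at equal
lengths. An event with no reads has no defined PSI and is reported `NA`,
not 0 - absence of evidence is not evidence of skipping.

`testEvents` compares exactly two groups. Group PSI is computed from
**summed** replicate counts (replicate PSIs are reported by `psiFromCounts`
when wanted); the p-value is a two-proportion binomial likelihood-ratio
test on the pooled length-normalised counts with one degree of freedom.
This engine is deliberately a stand-in: the hierarchical replicate model of
the upstream junction-count tool is out of scope, but the downstream
significance filter is applied to its output unchanged:

$$\text{significant} \iff |\Delta \mathrm{PSI}| \ge 0.10
 \;\wedge\; \mathrm{FDR} < 0.05
 \;\wedge\; (\textstyle\sum I \ge 5 \;\vee\; \sum S \ge 5),$$

with the $\Delta$PSI boundary inclusive ("$\ge 0.10$"), the FDR boundary
exclusive ("$< 0.05$"), the count rule disjunctive ("either ... $\ge 5$")
and totals summed across the replicates of both groups. FDR is
Benjamini-Hochberg over all tested events. A from-scratch rule oracle and
a from-scratch BH implementation back the property tests.

Intron retention is $\mathrm{IRR} = \text{intron reads}/\text{total reads}$
per intron, splicing efficiency $= 1 - \overline{\mathrm{IRR}}$ per group
(an exact identity, tested to machine precision), and groups are compared
by the two-sample Kolmogorov-Smirnov test - exact when either group has
fewer than 25 introns, asymptotic otherwise. Introns with zero total reads
are dropped with a logged count; a `pure` flag column, when present, is
trusted as given (its definition is internal to the upstream intron
annotation tool). Gel densitometry PSI is the inclusion band fraction
$I/(I+E)$.

# Patient-pair association

Expression is carried on the $-\Delta C_T$ scale (target minus reference,
negated, so higher means more snoRNA) and paired change on
$-\Delta\Delta C_T = -\Delta C_T(\mathrm{LN}) - [-\Delta C_T(\mathrm{primary})]$.
Pearson association reports $r$, the two-tailed p-value via
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom, and the OLS
line. Patients missing one tissue are excluded from paired analyses with
their ids messaged (exclusion, not imputation).

`thresholdSplit` implements lowest-p dichotomisation: candidate thresholds
are the midpoints between consecutive sorted unique expression values that
leave at least `minGroupSize` observations (default 3 - the smallest group
a t-test meaningfully handles) on each side; each candidate is scored by a
two-tailed Student's equal-variance t-test (Welch by flag), and the
candidate minimising p is returned, ties broken deterministically toward
the lowest threshold. Two points deserve emphasis:

* **No multiplicity correction is applied over candidates.** That is
  faithful to the published procedure, and it is optimistic: under a null
  slope the minimal p is below 0.05 far more often than 5% of the time.
  The test suite demonstrates this, and the full candidate trace is always
  returned so the optimisation is visible to users.
* Zero-variance groups make the t statistic 0/0; we define p = 1 when the
  group means agree and p = 0 when they differ, which keeps the constant-PSI
  case well-defined (all candidates tie, lowest threshold wins).

# What the simulators emulate - and what they do not

Each generator draws all randomness from one explicit seed and restores the
session RNG state, so identical calls are bit-identical and nothing leaks
between calls. Noise models are the simplest ones matching each platform's
support, chosen once:

| input | model |
|---|---|
| microarray intensities | per-probe base level $2^{U(5,12)}$, log2-normal noise (default sd 0.05), planted fold 2 in AxLN only |
| Ct values | Gaussian per replicate (default sd 0.1 cycles), triplicates |
| 3'-end counts | Poisson, site enrichment multiplicative |
| junction counts | Binomial per replicate at the group PSI |
| intron IRR | Beta around the group mean, concentration $1/\text{dispersion}$; reads Binomial |
| patient PSI | linear in $-\Delta C_T$, Gaussian noise, clamped to [0, 1] |

The defaults mirror the profiled study's layout where it is stated (two
baseline quadruplicates plus 6 MFP / 9 AxLN / 9 AxLN-LuM samples; a
snoRNA probe fraction of 0.124; 24 patient pairs) and otherwise use values
a practitioner would call realistic. None of the platforms' published
analyses state quantitative noise characteristics, so these defaults are
not calibrated to the study's data - passing recovery tests shows the
statistics behave correctly under clean, well-specified noise, not that
they would achieve the same operating characteristics on real arrays or
libraries, which carry batch structure, probe cross-hybridisation,
overdispersion and mapping artifacts that the generators deliberately omit.
Read-level simulation (FASTQ, alignment) is likewise out of scope: the
sequencing modules start at BED alignments and count tables.

# Numerical conventions and problem sizes

Degenerate inputs are handled explicitly rather than by coercion: undefined
PSI and gel PSI are `NA`; undetermined Cts are `NA` and propagate to
below-detection results; zero-variance correlations raise errors; zero-read
introns are dropped with a count. Percentiles interpolate linearly; all
threshold boundaries are as stated above; ties in the threshold search
break low.

The shipped test suite and acceptance script size their simulations so the
whole pipeline is exercised at meaningful power on a desktop: 20 seeds of a
1000-probe array for selection recovery, 200 samples for Nm-VAQ accuracy,
50 WT/KO track pairs for differential site detection, 2000 events times
several seeds for null calibration of the splicing filter, 2000 introns for
the KS contrast, and 50 seeds of 24 patient pairs for slope recovery.
Headline counts from the original sequencing analyses (thousands of events
and genes) require the deposited datasets and are intentionally not
reproduced at this scale.

# A worked example

```{r example}
sim <- simulateMicroarray(microarrayDesign(nProbes = 300, seed = 7))
sel <- selectAxlnSignature(sim$matrix)
table(selected = sel$selected, planted = rownames(sel) %in%
        truthParameters(sim$truth)$planted_probes)

hypergeometricEnrichment(N = 10043, K = 1245, n = 30, k = 20)[c("pUpper", "fold")]

plate <- simulateNmvaqPlate(c(wt = 0.9, ko = 0.1), seed = 7)$plate
vapply(c("wt", "ko"), function(s)
  nmvaqPercentMethylation(plate, s)$percentMe, numeric(1))

tracks <- simulateEndCountTracks(seed = 7)$tracks
differentialSites(nmScoreTrack(tracks$WT), nmScoreTrack(tracks$KO))
```

# Known limitations

* The per-event splicing p-value is a pooled-count likelihood-ratio test,
  not a replicate-aware hierarchical model; its null calibration is tested,
  but it will be anticonservative under strong between-replicate
  overdispersion.
* The RibOxi site-calling thresholds are defaults, not assay constants;
  real libraries with very uneven coverage may need both thresholds tuned.
* The lowest-p threshold split is reported uncorrected by design; treat its
  p-value as descriptive.
* Generators model clean platform noise only (see above).
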