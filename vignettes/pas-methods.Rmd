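---
title: "Methods: SNP-barcode authentication of xenograft samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-barcode authentication of xenograft samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasbarcode)
```

This vignette documents the models, parameters and design choices behind
`pasbarcode`: how the two-channel amplification signal is modeled, how
genotypes and contamination are called from it, and what the synthetic-data
generator does and does not emulate.

## The barcode and its discriminatory power

A sample's barcode is its vector of categorical genotype calls over a fixed
panel of biallelic SNP assays (default 32, of which 3 are Y-linked). Three
of the Y probes and five autosomal probes in the default panel carry their
published assay and rs identifiers; the remaining 24 commercial probe IDs
are not public, so the panel fills them with clearly synthetic placeholders
(`SYN_*`) spread across the autosomes. Panel size and content are fully
configurable, and toy panels (down to a single locus) are used throughout
the test suite.

Two unrelated samples match at one locus with probability
$\sum_j g_j^2$ over the genotype frequencies $g_j$, and loci multiply.
Because the true population frequencies of the commercial panel are
unpublished, all discriminatory-power outputs state their frequency
assumption explicitly (default: Hardy–Weinberg equilibrium at allele
frequency 0.5 per locus, the maximum-entropy assumption for a human-ID
panel, giving 0.375 per locus). "A random match in a biobank of $N$" is
deliberately reported two ways, since the phrase is ambiguous: the per-pair
probability $p$, and the birthday bound $1-(1-p)^{\binom{N}{2}}$ over all
pairs, computed in `log1p`/`expm1` form so values of order $10^{-14}$ do
not underflow.

## The amplification signal model

The package needs a generative model of the two-channel qPCR signal; the
platform it emulates publishes no amplification equations, so the model is
the package's own, chosen to be the simplest one that reproduces the two
signatures the method exploits:

* endpoint angle shifts under allelic imbalance, and
* late minor-channel amplification under dilute contamination.

Each channel $i$ of a locus carries template fraction $q_i$, normalized so
a pure diploid homozygote has $q = 1$ (an ordinary heterozygote has
$q_1 = q_2 = 1/2$; copy-number variants and mixtures produce other values).
The channel follows a logistic curve with growth rate $r$ per cycle,
anchored so that it crosses a fixed instrument detection level exactly at

$$Ct_i = ct_0 - \log_2 q_i,$$

i.e. one cycle of delay per template halving — the defining Ct law of
real-time PCR and the only quantitative assumption the downstream
estimators rely on. Channel plateaus are proportional to allele fraction
(the two probes share amplification resources, so endpoint fluorescence
saturates in proportion to each allele's share), which makes the endpoint
angle $\theta = \mathrm{atan2}(f_2, f_1)$ encode the allele ratio: pure
homozygotes on the axes, heterozygotes at 45°, a 1:2 imbalance at
$\mathrm{atan}(2) \approx 63°$.

Noise has three interpretable components, all seeded:

| parameter | meaning | default |
|---|---|---|
| `plateau_cv` | log-normal CV of each channel's plateau | 0.05 |
| `ct_sd` | Gaussian jitter on each channel's crossing cycle (cycles) | 0.15 |
| `baseline_sd` | additive per-cycle baseline noise (a.u.) | 1.5 |

The remaining model constants are `cycles = 40`, `ct0 = 22`,
`plateau = 2000` a.u. for a pure homozygote, `growth_rate = 0.7` per cycle
and `detect_level = 10` a.u. With these defaults a 1/32 contaminant at an
informative locus rises around cycle 27 — well inside the cycle budget and
easily separated from baseline noise — while its endpoint angle
($\approx 1.8°$) stays inside the homozygous band. That matches the
intended behavior: dilute mixtures are endpoint-ambiguous but
rise-cycle-detectable, so detection must integrate curve shape, not just
endpoint clusters.

At an informative locus (reference homozygous, contaminant opposite
homozygous) the exact model law for the minor channel's lag is
$\log_2\!\frac{1-f}{f}$ cycles; the commonly quoted $\log_2(1/f)$
approximation is accurate to within one cycle over the whole serial
dilution $f \in \{1/2, \dots, 1/32\}$, and the test suite verifies the
lag at that tolerance on integer rise cycles. Internally, threshold
crossings are also computed with linear interpolation between cycles;
fraction estimates use the interpolated values for precision while the
reported `rise1`/`rise2` remain the first integer crossing cycle.

## Genotype calling

Calls are made from the endpoint summary with magnitude gates followed by
angle bands:

* `NOAMP` below 200 a.u. endpoint magnitude;
* `UNDET` below 800 a.u. — a deliberately conservative rule: weak signal is
  never given a confident genotype even at a canonical angle, which is
  exactly how inefficiently amplifying samples acquire their characteristic
  undetermined calls without any contamination;
* otherwise `HOM1` under 15°, `HET` in 35–55°, `HOM2` above 75°, and
  `UNDET` in the gaps (where allelic imbalance and mid-fraction mixtures
  land).

Band edges are configurable through `pas_thresholds()`. The defaults put
roughly five standard deviations of angle noise between a true
heterozygote and its band edges at default noise, and leave the 1:2
imbalance angle (63.4°) in a gap, so copy-number-shifted loci read as
undetermined rather than being mis-called. Call quality decays linearly
with distance from the band center and with low magnitude; for `NOAMP`
calls the quality instead reflects how convincingly silent the locus is.

## Contamination detection and triage

Per locus, the evidence against an expected reference call is:

* `late_minor_amplification` — the expected call is homozygous, yet the
  opposite allele's channel crosses the rise threshold within the cycle
  budget;
* `deviation_deg` — angular distance to the nearest canonical cluster
  (0/45/90°), an intensity-invariant measure of endpoint displacement;
* `weak_amplification` — magnitude between the no-amplification and
  confident-call cutoffs.

A locus is *flagged* when adequately amplified and showing either late
minor amplification or deviation above 10°. The sample-level disposition
then is:

* `CONTAMINATED` — at least `k_flagged = 3` flagged loci. Multi-locus
  corroboration is required by design: any single probe can misbehave, and
  the method's strength is precisely the integration across the panel.
* `INEFFICIENT_AMPLIFICATION` — weak or undetermined loci exist but the
  angles stay canonical and fewer than 3 loci are flagged. This is the
  amplification-failure signature: faint but correctly oriented curves.
* `CLEAN` otherwise.

Loci inside a reference's annotated copy-number regions are exempt from
deviation-based evidence for that reference, since stable allelic
imbalance there is a property of the line, not contamination. (They still
contribute late-minor evidence, which a pure imbalance cannot produce at a
homozygous locus.)

The implied second contributor is chosen best-effort: each other registry
reference is scored by the fraction of flagged loci whose implicated minor
allele it carries, and the best candidate is reported only when it beats
the runner-up by a configurable margin (default 0.1). Identifying the
contaminant is intrinsically harder than detecting the mixture, and the
report is confidence-gated accordingly, never guaranteed. The contaminant
fraction is the median over expected-homozygous flagged loci of the
rise-cycle fraction estimate, mapped through the candidate's allele dosage
(2 copies assumed when no candidate is named).

## Validation verdicts

Sample-level comparison counts, over loci where both profiles are
determined: strong mismatches (opposite homozygotes — impossible without a
genotype difference), weak mismatches (homozygote vs heterozygote — one
allele's worth of discrepancy, which copy-number imbalance can also
produce), and undetermined loci. Y-linked loci at which both samples show
no amplification are concordant female dropout and are excluded from every
count, so sex-matched comparisons are never penalized.

A sample is `VALIDATED` against its expected reference when that reference
is the unique concordance maximum over the registry with zero strong and
at most two weak mismatches; `MISMATCHED` when a different reference fits
while the expected one does not (the mis-label scenario); `INCONCLUSIVE`
when four or more loci are undetermined without signal-level mixture
evidence, or when the best reference is tied (ties are reported, never
silently broken). When traces are available every sample also receives the
signal-level disposition above, and a `CONTAMINATED` disposition upgrades
the verdict to `CONTAMINATION_SUSPECT`.

The mismatch thresholds are a design choice the source platform leaves
open. They are anchored to the observed structure of reference cohorts:
distinct patients differ at many loci (a dozen or more even for the
closest pair), so zero strong mismatches is a safe requirement; weak
mismatches up to two tolerate copy-number artifacts; and an
undetermined-enrichment trigger of four matches the scale at which
problematic cohort groups visibly accumulate white squares. All are
configurable through `pas_thresholds()`.

## Clustering and heatmaps

The clustering distance is categorical:
$d = (\text{strong} + 0.5\,\text{weak}) / n_\text{informative}$, 0 for
identical barcodes and defined as 1 when no informative locus is shared.
Agglomeration uses average linkage by default (complete linkage
available). The qualitative reproduction target is structural — no
inter-patient matches, same-patient pairs merging at height zero,
contaminated samples separating from the validated group — not any
particular leaf order, which is why the tests assert merge heights and
partitions rather than dendrogram layout. Heatmaps use the conventional
color map (allele-1 homozygote red, allele-2 blue, heterozygote green,
no-amplification/undetermined white) and are exported together with a TSV
of the ordered call matrix that round-trips the calls exactly.

## What the simulator emulates — and what it does not

Emulated: Hardy–Weinberg genotypes at configurable allele frequencies;
sex-dependent Y dropout (females have no Y template, males are
hemizygous); 1–3-contributor DNA mixtures as fraction-weighted template
averages (mixing purified DNA, as a wet-lab dilution series would);
copy-number regions via arbitrary per-locus allele copy numbers;
amplification inefficiency as magnitude attenuation that leaves allele
ratios untouched; and full trace-level noise.

Not emulated: probe cross-hybridization, dye bleed-through and optical
normalization; differential DNA extraction efficiency between mixed cell
populations; engraftment dynamics of competing clones (mixtures have fixed
fractions); mouse-DNA contamination; and genotyping error processes other
than low signal. Consequently, a passing simulation suite demonstrates the
*decision logic* — calling bands, integration across loci, triage between
mixture and inefficiency, power at given noise — under the stated noise
model, not instrument-specific performance. The detection-limit figure,
in particular, is conditional on the noise defaults above and on contributors
drawn at allele frequency 0.5.

## Numerical choices and degenerate inputs

* Rise cycles: first integer cycle strictly above threshold; interpolated
  crossings are used internally for fraction estimates. A channel whose
  realized plateau never reaches the detection level is treated as
  non-amplifying.
* `atan2(0, 0)` (a fully silent locus) reports angle 0 with magnitude 0 and
  is gated out by the magnitude rules before any angle is interpreted.
* Fraction estimates return exactly 0 or 1 for single-channel
  amplification, and fall back to the endpoint ratio when no usable rise
  cycles exist at adequate magnitude.
* An empty registry, an empty sample batch, and single-profile clustering
  inputs are all rejected or returned as valid empty objects, never
  silently guessed; parsers reject structural ambiguity (duplicate rows,
  missing columns, foreign assays) and only degrade with a warning for
  unknown call strings (to `UNDET`) and missing per-sample assay rows (to
  `NOAMP`).
* All stochastic entry points take an explicit integer seed and are
  bit-reproducible under it; seeded draws run in an isolated RNG scope so
  library calls never perturb a caller's stream.

## Problem sizes used by the test suite

The suite checks statistical properties at sizes chosen to make the checks
meaningful rather than exhaustive: genotype-calling consistency and the
no-collision property at 10,000 draws; the detection power curve and
false-positive rate at 200 replicates per condition; per-locus
false-positive rates at 1,000 replicates; pure-sample CLEAN rates at 300
replicates; the Monte-Carlo collision cross-check at 2,000 panels of 10
profiles over 4 loci (a regime where the collision probability is
non-degenerate, ~0.59, so the comparison has power); and the end-to-end
cohort rehearsal at 75 samples. The headline recomputation in
`scripts/acceptance.R` uses 200 replicates per condition.

## Known limitations

* Contaminant identification (as opposed to detection) is best-effort and
  degrades when the registry contains many similar profiles or the mixture
  involves more than two contributors.
* Verdicts assume the registry reference is correct; a corrupted reference
  propagates as systematic mismatch, which shows up as `MISMATCHED`
  clusters rather than being auto-corrected.
* Match probabilities ignore population substructure and kinship; they are
  upper bounds on discriminatory power only under the stated frequency
  assumptions.
* The Ct-law fraction estimator saturates for very small fractions once
  the minor channel's plateau approaches the detection level; with the
  default parameters this begins below ~1/64.
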