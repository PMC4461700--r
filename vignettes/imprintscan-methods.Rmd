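---
title: "Methods: quantification, classification and UPD confirmation in imprintscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, classification and UPD confirmation in imprintscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
library(dplyr)
```

## The assay model

The screen quantifies methylation at imprinted differentially methylated
regions (DMRs) by comparing two aliquots of the same genomic DNA: one
digested with the methylation-sensitive enzyme HpaII, one undigested. Only
methylated copies of a DMR survive digestion and amplify; amplicons without
an HpaII site (the *reference* amplicons) amplify equally from both
aliquots and anchor the quantification. At each panel DMR exactly one
parental allele is normally methylated (KCNQ1OT1 and SNRPN maternal; H19
and MEG3 paternal), so a normal sample presents one methylated copy out of
two at every DMR.

For amplicon $a$ with peak area $A(a)$, the within-sample relative area is
$r(a) = A(a) / \sum_{\mathrm{ref}} A$, and each $r(a)$ is normalized to the
arithmetic mean of the control cohort's relative areas for the same
amplicon and condition. This yields, per DMR locus:

* $M$, the normalized digested value (methylation), and
* $D$, the normalized undigested value (dosage),

both with expectation 1 in samples drawn from the control population. The
statistic cancels sample loading, amplicon efficiency, and any global
rescaling of the instrument (this invariance is property-tested).

**Why reference-only normalization is the default.** The assay's verbal
description divides by the sum of *all* peak areas. Both denominators are
implemented (`mode = "all_peaks"` and `"reference_only"`), but the default
is reference-only because it makes $M$ linear in methylated-copy number:
with a mosaic fraction $c$ of cells having lost methylation on the normally
methylated allele, noise-free data give exactly $M = 1 - c$, so
`percent_loss` $= 100\,(1-M)$ reads off the mosaic fraction (80% and 40%
loss scenarios are recovered exactly in the acceptance tests). The
all-peaks denominator shrinks when the DMR peak shrinks, inflating the
ratio ($M_\text{all} \ge M_\text{ref}$, also tested); it is retained for
fidelity and comparison.

$M$ is deliberately *not* dosage-corrected before classification — the
normal range is applied to $M$ itself, with $M/D$ (`M_per_copy`) always
reported alongside. This keeps the methylation and dosage axes of the
report independent, mirroring how the two bars are read side by side.

## Classification

A control-normalized value within $1 \pm 0.2$ is normal, inclusive at both
ends (0.8 and 1.2 are normal; boundary behavior is pinned by tests).
Methylation classes: `COMPLETE_LOM` at $M \le 0.1$, `PARTIAL_LOM` on
$(0.1, 0.8)$, `NORMAL` on $[0.8, 1.2]$, `GOM` above. The 0.1 line between
complete and partial (mosaic) loss is this package's numeric choice where
practice draws the line verbally; it is exposed in `normal_range()`.
Dosage uses the same range for `LOSS`/`NORMAL`/`GAIN`. Applying the range
to dosage as well as methylation is a design choice: both values are on
the same control-normalized scale, and a heterozygous deletion or
duplication moves $D$ to 0.5 or 1.5, far outside it.

**Sample positivity is keyed to methylation only**: a sample is screen
positive when $M$ is outside the normal range at any locus, which is the
decision rule the assay's confirmation workflow is built around. Dosage
abnormalities are still classified and reported per locus (a duplication
with normal methylation appears in the calls table, flagged by its dosage
class) but do not, alone, make a sample methylation-screen positive.
A sample with abnormal methylation at two or more loci is flagged as a
*multilocus methylation defect* candidate.

The mechanism rule table conditions on dosage: loss of methylation at
normal dosage is an epimutation or a UPD of the unmethylated parent (for a
*partial* loss epimutation is listed first, since constitutional UPD is
rarely mosaic; for a *complete* loss UPD first); gain at normal dosage
lists UPD of the methylated parent first, then a hypermethylation
epimutation — the trio test separates them; gain of methylation with
dosage gain indicates duplication of the methylated allele; normal or low
methylation with dosage gain, duplication of the unmethylated allele;
dosage loss, a deletion. Ordering encodes prior plausibility only —
hypotheses are never suppressed, and every non-normal call carries a
recommendation to confirm by an orthogonal methylation assay (MS-MLPA)
plus microsatellite segregation.

**Blind-test ordering.** `run_screen()` computes all methylation and
dosage calls before looking at any trio data; reconciliation then only
edits the mechanism annotations (a BIPARENTAL verdict removes the UPD
hypotheses, promoting epimutation by exclusion; a matching UPD verdict is
promoted and marked confirmed). The call fields other than mechanisms are
invariant to the presence of the trio file, which is property-tested.

## Trio segregation and its power

Per marker, the classifier enumerates explanations of the child genotype:
biparental (one allele attributable to each parent), maternal-only /
paternal-only (all child alleles from one parent *and* no biparental
assignment exists), Mendelian error (no explanation), and triallelic
(three distinct alleles — duplication evidence, with maternal/paternal
copy counting when every allele is attributable to exactly one parent,
e.g. two maternal plus one paternal). When a biparental and a uniparental
explanation coexist the marker is uninformative — informativeness is
decided by explanation enumeration, not by heterozygosity shortcuts, and
the implementation is tested for exact agreement with a brute-force
transmission-enumeration oracle over all trios with alleles in 1..4.

Aggregation (`call_upd()`) requires at least `min_supporting = 3`
concordant informative markers for any verdict, zero opposite-parent
markers for a UPD verdict, and tolerates zero Mendelian errors by default
(any error demotes the trio to INCONSISTENT). Disomy type is ISODISOMY
when all supporting markers show a homozygous child, HETERODISOMY when all
show both alleles of the implicated parent, MIXED otherwise. Triallelic
markers never count toward UPD support; a duplication-plus-UPD case is
reported as a UPD verdict from the biallelic markers with the triallelic
markers counted separately.

**Marker-panel power.** Under heterodisomy a marker supports UPD only when
the father shares no allele with the transmitted maternal genotype. With
$n$ equifrequent alleles the exact per-marker support probability is

$$p = \frac{n-1}{n}\Big(\frac{n-2}{n}\Big)^2 +
      \frac{1}{n}\Big(\frac{n-1}{n}\Big)^2,$$

and the panel power is the binomial tail $P(X \ge 3)$,
implemented in `upd_marker_power()`:

```{r power}
upd_marker_power(8, 4, 3)$power    # small panel, common alleles: ~0.52
upd_marker_power(12, 8, 3)$power   # package default design: >0.99
```

A panel of 8 markers with 4 equifrequent alleles confirms barely half of
true heterodisomy trios — far too weak for a confirmation assay — so the
simulator's default trio design is 12 markers with 8 equifrequent alleles
(power ≈ 0.996), chosen from this calculation. The per-marker probability
is cross-checked against simulation in the test suite, and the 1,000-trio
recovery test runs at the default design.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the molecular
structure the statistic assumes:

* per-locus parental copy numbers and per-allele methylation fractions
  (`EpigenotypeSpec` rows; a mosaic loss fraction $c$ enters as
  methylation $1-c$ on the normally methylated allele);
* digest survival: undigested template is $cn_m + cn_p$; digested template
  is the methylated copies plus, under incomplete digestion, a fraction
  $(1-dc)$ of the unmethylated copies (a single global fraction, not
  per-site). The resulting inflation of $M$ has a closed form that is
  asserted exactly in the tests;
* reference amplicons modeled without HpaII sites (template 2 in both
  aliquots) — the structural assumption that makes the statistic work;
* per-amplicon efficiencies, per-sample loading factors (lognormal,
  sdlog 0.3 — ordinary input-DNA variability; both cancel exactly), and
  multiplicative lognormal per-peak noise, default $\sigma = 0.05$
  (capillary peak areas are positive and scale-proportional; the
  magnitude is an engineering default, exposed in the API, as the real
  assay's noise is not published);
* zero-template amplicons yield no peak row, exercising the
  missing-peak path of the pairing step.

It does **not** model PCR saturation or inter-amplicon competition, dye
pull-up, stutter, size-call jitter, or population allele-frequency
spectra beyond equifrequent — so passing tests show the estimator and its
invariances are correct under the assay's idealized structure, not that a
particular wet-lab run will be this well behaved.

`patients_table1()` packages the five canonical positive archetypes (80%
mosaic LOM at KCNQ1OT1; a paternal 11p15 duplication raising dosage at
both H19 and KCNQ1OT1 with H19 hypermethylation; 40% mosaic LOM at SNRPN;
UPD(14)pat and UPD(14)mat signatures at MEG3), which reproduce the
hypo/hyper alteration pattern and its mechanism calls end to end.

**Expected false positives at cohort scale.** With per-peak
$\sigma = 0.05$, the log of a normalized value has standard deviation
$\approx \sqrt{\sigma^2 + \sigma^2/k + \sigma^2(1+1/k)/n_c} \approx 0.057$
(numerator peak, $k = 4$ reference peaks, $n_c = 20$ controls), so a
normal locus lands outside $[0.8, 1.2]$ with probability $\sim 7 \times
10^{-4}$. Screening 400+ patients at four loci therefore *expects* on the
order of one borderline false-positive methylation value per cohort — the
reason the workflow treats out-of-range values as screen positives to be
confirmed, not diagnoses. The test suite asserts the per-sample
false-positive fraction stays below 5%.

## Numerical and I/O choices

* Peak-to-amplicon assignment uses symmetric size windows; a peak inside
  two windows is an error, never nearest-wins (silent misassignment would
  corrupt the denominator). Unassigned peaks are excluded with a warning.
* Duplicate runs of one condition are an error — no silent replicate
  averaging. Samples missing a condition are dropped with a warning.
* A missing expected peak is recorded as area 0 with a flag; $D = 0$
  (complete deletion) yields `M_per_copy = 0` with a flag rather than an
  exception.
* The control baseline uses arithmetic means, minimum 5 controls
  (configurable; overridable with a propagated `LOW_CONTROL_N` flag), no
  outlier trimming; each control is additionally re-measured against a
  leave-one-out baseline and reported if out of range, never
  auto-excluded.
* Genomic intervals are 1-based inclusive (span $= end - start + 1$),
  matching clinical array nomenclature; report spans round half-up to
  integer kilobases or one-decimal megabases.
* Reports are written deterministically (no timestamps; provenance is
  input digests plus package version), so re-running on identical inputs
  is byte-identical.

## Problem sizes used in the tests

Unit tests run on 3-amplicon mini-panels with 5-control cohorts; the
recovery grids cover mosaic fractions $c \in \{0, 0.1, \ldots, 1\}$ and
parental copy numbers $0..3$; the stochastic calibration test uses 500
normal samples; the trio oracle grid is exhaustive over alleles 1..4
(1,000 trios); the UPD recovery test uses 1,000 simulated heterodisomy
trios; the cohort-scale acceptance test embeds the five archetypes among
412 patients with 20 controls at $\sigma = 0.05$. These sizes were chosen
as the smallest that exercise each property convincingly.

## Known limitations

* The default panel's amplicon sizes and reference loci are synthetic
  placeholders (structurally faithful, not a primer-level reconstruction
  of any published multiplex); the imprinting metadata is real.
* Only the three-distinct-allele route identifies duplications in trio
  data; allele dosage from peak ratios is not modeled.
* The screen cannot distinguish an imprinting-center microdeletion from a
  primary epimutation — that requires probe-level MS-MLPA data, which is
  out of scope (MS-MLPA appears only as a confirmation recommendation).
* Classification assumes one amplicon per DMR locus; multi-amplicon DMRs
  are reported per amplicon, not merged.
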