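# imprintscan

Screening for epimutations at imprinted loci from methylation-sensitive
restriction digest multiplex-PCR data.

## The problem

Imprinting disorders (Beckwith–Wiedemann, Silver–Russell, Angelman,
Prader–Willi, the UPD(14) syndromes) are caused by abnormal methylation at
differentially methylated regions (DMRs), where exactly one parental allele
is normally methylated. A cheap first-line screen works as follows: one
aliquot of genomic DNA is digested with the methylation-sensitive enzyme
HpaII (only methylated copies survive and amplify), another is left
undigested, and both are amplified in a semiquantitative multiplex PCR whose
products are resolved on a capillary analyzer. Comparing the two aliquots,
normalized to a control cohort, yields per-locus methylation and gene-dosage
values in one assay. `imprintscan` implements the quantification, the
epigenotype classification with mechanism hypotheses, and the trio
microsatellite segregation test that confirms or excludes uniparental disomy
(UPD) — plus a synthetic-data generator so the whole pipeline is testable
without patient DNA.

## The statistic

For amplicon *a* with peak area *A(a)* in one sample and condition
(digested or undigested), the relative area is

    r(a) = A(a) / Σ_ref A(ref)         (reference-amplicon denominator, default)
    r(a) = A(a) / Σ_all A(a')          (all-peaks denominator, classical)

where the reference amplicons carry no HpaII site and amplify equally in
both aliquots. Each relative area is then normalized to the mean relative
area of the control cohort. For a DMR locus this gives

* **M** — normalized digested value (methylation; ≈ 1 in normal samples),
* **D** — normalized undigested value (dosage; ≈ 1 for two copies).

With the reference-only denominator M is linear in methylated-copy number:
a mosaic loss of methylation in a fraction *c* of cells gives exactly
M = 1 − *c*, so `percent_loss = 100·(1 − M)` recovers the mosaic fraction.
Values within **1 ± 0.2** (inclusive) are normal; M below 0.8 is a partial
(or, at ≤ 0.1, complete) loss of methylation, above 1.2 a gain; D is
classed on the same range as LOSS/NORMAL/GAIN. Each abnormal
(M-class, D-class) pair maps to ordered mechanism hypotheses — epimutation,
UPD of one parent, duplication of the methylated or unmethylated allele,
deletion — and UPD is then tested directly by segregation of trio
microsatellites (`classify_markers()` + `call_upd()`), with
`upd_marker_power()` giving the exact probability that a marker panel can
confirm a true disomy.

## Worked example

Simulate a noise-free cohort embedding the five classic alteration
archetypes (80% mosaic LOM at KCNQ1OT1; paternal 11p15 duplication; 40%
mosaic LOM at SNRPN; UPD(14)pat; UPD(14)mat) and screen it:

```r
library(imprintscan)
panel  <- default_panel()
specs  <- patients_table1(panel)
names(specs) <- sprintf("P%03d", 1:5)
cohort <- simulate_cohort(panel, n_patients = 8, n_controls = 6,
                          patient_specs = specs, noise_sigma = 0, seed = 7)
scr <- run_screen(cohort$peaks, panel, controls = cohort$controls)
scr
```

```
Imprinting epimutation screen (panel_imprint4 v1.0, mode reference_only)
  samples screened: 8 | controls: 6 
  positive: 5 | multilocus candidates: 0 
  abnormal calls:
    P001 KCNQ1OT1: M=0.20 D=1.00 PARTIAL_LOM/NORMAL [EPIMUTATION, UPD_PATERNAL]
    P002 KCNQ1OT1: M=1.00 D=1.50 NORMAL/GAIN [CNV_DUP_UNMETHYLATED_ALLELE]
    P002 H19: M=2.00 D=1.50 GOM/GAIN [CNV_DUP_METHYLATED_ALLELE]
    P003 SNRPN: M=0.60 D=1.00 PARTIAL_LOM/NORMAL [EPIMUTATION, UPD_PATERNAL]
    P004 MEG3: M=2.00 D=1.00 GOM/NORMAL [UPD_PATERNAL, EPIMUTATION]
    P005 MEG3: M=0.00 D=1.00 COMPLETE_LOM/NORMAL [UPD_MATERNAL, EPIMUTATION]
```

Reading the output: P001's M = 0.20 at KCNQ1OT1 is an 80% loss of
methylation (`percent_loss = 80`) at normal dosage — an epimutation or a
paternal UPD, which the trio test then separates; P002 shows the
methylated-allele duplication signature at H19 (M = 2.0 with D = 1.5);
P004/P005 show the two UPD(14) signatures at MEG3 with normal dosage.
Adding a trio file (`trios =`) reconciles these hypotheses: a BIPARENTAL
verdict reduces P001's mechanisms to a confirmed epimutation, a matching
UPD verdict is promoted and marked confirmed. `tidy(scr)`, `glance(scr)`
and `autoplot(scr)` give the flat call table, the one-row cohort summary,
and the bar-chart view of M and D per locus; `write_report(scr, dir)`
writes `report.json`, `calls.tsv` and `measurements.tsv` deterministically.

A command-line wrapper with `screen`, `simulate` and `upd` subcommands is
in `inst/scripts/imprintscan.R`.

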