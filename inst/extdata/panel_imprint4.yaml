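# Default four-locus imprinting panel for the methylation-sensitive digest
# multiplex. DMR metadata (band, methylated parental allele, associated
# syndromes) is real; amplicon sizes and the reference amplicons are
# synthetic placeholders with non-overlapping assignment windows.
name: panel_imprint4
version: "1.0"
amplicons:
  - name: KCNQ1OT1_DMR
    locus: KCNQ1OT1
    expected_size: 150
    size_tolerance: 2
    kind: DMR
    chrom_band: 11p15
    methylated_parent: maternal
    hypo_syndrome: Beckwith-Wiedemann syndrome
    hyper_syndrome: ~
  - name: H19_DMR
    locus: H19
    expected_size: 166
    size_tolerance: 2
    kind: DMR
    chrom_band: 11p15
    methylated_parent: paternal
    hypo_syndrome: Silver-Russell syndrome
    hyper_syndrome: Beckwith-Wiedemann syndrome
  - name: SNRPN_DMR
    locus: SNRPN
    expected_size: 182
    size_tolerance: 2
    kind: DMR
    chrom_band: 15q12
    methylated_parent: maternal
    hypo_syndrome: Angelman syndrome
    hyper_syndrome: Prader-Willi syndrome
  - name: MEG3_DMR
    locus: MEG3
    expected_size: 198
    size_tolerance: 2
    kind: DMR
    chrom_band: 14q32
    methylated_parent: paternal
    hypo_syndrome: UPD(14)mat syndrome
    hyper_syndrome: UPD(14)pat syndrome
  - name: REF1
    locus: REF1
    expected_size: 118
    size_tolerance: 2
    kind: REFERENCE
    chrom_band: 2q37
  - name: REF2
    locus: REF2
    expected_size: 134
    size_tolerance: 2
    kind: REFERENCE
    chrom_band: 5q31
  - name: REF3
    locus: REF3
    expected_size: 214
    size_tolerance: 2
    kind: REFERENCE
    chrom_band: 7q22
  - name: REF4
    locus: REF4
    expected_size: 230
    size_tolerance: 2
    kind: REFERENCE
    chrom_band: 17q21
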