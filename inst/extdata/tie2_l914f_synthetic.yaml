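# Synthetic TIE2 L914F amplicon fixture.
#
# The amplicon is a SYNTHETIC stand-in: it starts with the published
# forward PCR primer (CAGGGCCACTGATGAGTCGAT) and ends with the reverse
# complement of the published reverse primer (TCGGCAGCGAAGTGAAGGAG), but
# the internal sequence, the 10 bp flank anchors and the 20 bp editing
# window are invented. The donor edit models the L914F change as a single
# C>T substitution (CTC leucine codon at window positions 8-10 -> TTC
# phenylalanine); the true DNA-level codon context is an assumption, not a
# genomic extract.
amplicon_id: TIE2_L914F_synthetic
amplicon_fasta: tie2_l914f_synthetic.fa
left_flank: ACCTGGAGTA
right_flank: GTCATGGAAC
donor_edits:
  - "8:C>T"
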