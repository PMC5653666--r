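locus_id: synthetic_amplicon
genomic_contig: chrS
genomic_offset: 145000001
flank_len: 10
guide_seq: TCAAGGATCTGGCTATACCC
pam_seq: AGG
guide_strand: +
frame_offset: 0
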