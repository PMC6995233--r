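species	copy	exons_present	contiguity	gap_kind	nt_identity	orf_codons	aa_identity	expressed
rat	1	1-6	full_length	none	88.4	0	NA	no
rat	2	6	partial	none	87.4	0	NA	no
rat	3	6	partial	none	87.4	0	NA	no
guinea_pig	1	4-6	partial	none	80.1	0	NA	no
rabbit	1	1-6	gapped	n_run	87.7	0	NA	no
dog	1	1-6	full_length	none	88.3	123	99.2	no
dolphin	1	1-6	full_length	none	93.4	199	100	no
dolphin	2	1-6	full_length	none	83.8	199	93.0	no
dolphin	3	1-6	full_length	none	89.8	90	83.3	no
dolphin	4	1-6	full_length	none	86.2	0	NA	no
megabat	1	1-6	full_length	none	87.1	0	NA	no
microbat	1	1-6	full_length	none	89.5	199	91.0	untestable
microbat	2	1-6	full_length	none	81.5	0	NA	untestable
opossum	1	1-6	full_length	none	86.6	96	77.1	no
platypus	1	2,3	fragmented	none	89.8,87.7	0	NA	untestable
marmoset	1	1-6	full_length	none	91.8	123	97.6	untestable
marmoset	2	1-6	full_length	none	89.2	199	98.5	untestable
marmoset	3	1-6	gapped	insertion	90.9	0	NA	untestable
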