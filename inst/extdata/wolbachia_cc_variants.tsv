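locus	founder_allele	variant_allele	n_diffs	single_seen_elsewhere	allele_seen_elsewhere
wsp	1	5	18	NA	NA
wsp	5	3	8	NA	NA
wsp	12	4	16	NA	NA
ftsZ	2	1	1	FALSE	NA
groEL	8	4	4	NA	NA
groEL	12	11	2	NA	TRUE
trmD	1	3	1	TRUE	NA
trmD	1	10	15	NA	NA
trmD	1	6	7	NA	NA
trmD	1	14	9	NA	NA
trmD	1	2	1	TRUE	NA
trmD	1	5	2	NA	FALSE
trmD	8	17	9	NA	NA
trmD	8	15	8	NA	NA
trmD	9	11	1	TRUE	NA
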