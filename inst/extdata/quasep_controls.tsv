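# Published pyrosequencing (QUASEP) maternal-allele percentages for the test
# gene and control genes, one row per reciprocal cross direction (cross_label
# = which accession was the mother).  published_mean is the mean maternal
# percentage as printed; mean_consistent marks rows whose printed mean equals
# the arithmetic mean of the two printed directions (the CDC48A and PHE1
# means were evidently computed from unrounded replicate data and are kept
# for context only, not as numeric oracles).
gene	gene_id	cross_label	maternal_pct	published_mean	published_status	mean_consistent
CDC48A	At3g09840	Col-0	100.0	90.4	MEG_test	FALSE
CDC48A	At3g09840	C24	80.5	90.4	MEG_test	FALSE
FWA	At4g25530	Col-0	92.1	94.6	MEG_control	TRUE
FWA	At4g25530	Ler-0	97.1	94.6	MEG_control	TRUE
PHE1	At1g65330	Col-0	27.4	21.1	PEG_control	FALSE
PHE1	At1g65330	Ler-0	12.8	21.1	PEG_control	FALSE
PHE2	At1g65330	Col-0	56.3	45.8	biallelic	TRUE
PHE2	At1g65330	Ler-0	35.3	45.8	biallelic	TRUE
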