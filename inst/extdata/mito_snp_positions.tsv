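position_id	chromosome	position	gene	context	nonsynonymous
ChMt1-22156	chMt1	22156	NA	intergenic	NA
ChMt1-110241	chMt1	110241	NA	intergenic	NA
ChMt1-110242	chMt1	110242	NA	intergenic	NA
ChMt1-167288	chMt1	167288	NA	intergenic	NA
ChMt1-167297	chMt1	167297	NA	intergenic	NA
ChMt2-30884	chMt2	30884	NA	intergenic	NA
ChMt3-4214	chMt3	4214	rps4	exon	FALSE
ChMt3-30033	chMt3	30033	nad2	intron	TRUE
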