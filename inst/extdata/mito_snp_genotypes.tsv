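sample	ChMt1-22156	ChMt1-110241	ChMt1-110242	ChMt1-167288	ChMt1-167297	ChMt2-30884	ChMt3-4214	ChMt3-30033
P4-103	C	G	C	A	A	C	C	C
P4-105	C	G	C	A	A	C	C	G
P4-106	C	G	C	A	A	C	A	C
P8-173	C	G	C	A	A	C	A	A
P8-197	C	G	C	A	A	C	A	A
P8-206	C	G	C	C	C	C	C	G
P9-120	C	G	C	A	A	C	C	G
P9-121	A	G	C	A	A	A	A	G
P9-122	C	G	C	A	A	C	C	G
P9-133	A	T	A	A	A	A	A	G
P13-1	C	G	C	A	A	C	C	G
P13-2	C	G	C	A	A	C	C	G
P13-3	C	G	C	A	A	C	C	G
P15-121	C	G	C	A	A	C	C	G
P15-123	C	G	C	A	A	C	C	G
P15-124	C	G	C	A	A	C	C	G
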