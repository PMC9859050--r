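sample	population	locality
P4-103	P4	Kopna Gora
P4-105	P4	Kopna Gora
P4-106	P4	Kopna Gora
P8-173	P8	Kopytkowo
P8-197	P8	Kopytkowo
P8-206	P8	Kopytkowo
P9-120	P9	Bemowo Piskie
P9-121	P9	Bemowo Piskie
P9-122	P9	Bemowo Piskie
P9-133	P9	Bemowo Piskie
P13-1	P13	Rudne
P13-2	P13	Rudne
P13-3	P13	Rudne
P15-121	P15	Zabiele
P15-123	P15	Zabiele
P15-124	P15	Zabiele
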