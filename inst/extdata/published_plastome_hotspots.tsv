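region	snps	indels
ndhD--ccsA	15	18
rps4--rps16	6	6
trnL(UAG)--ndhF	6	5
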