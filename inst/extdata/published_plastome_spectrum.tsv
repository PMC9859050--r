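class	kind	percent
A<->C	transversion	9.38
A<->T	transversion	37.5
G<->C	transversion	3.12
G<->T	transversion	18.75
A<->G	transition	14.06
C<->T	transition	17.19
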