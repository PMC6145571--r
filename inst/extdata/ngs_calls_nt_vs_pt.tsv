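tissue	mirna_id	direction
lung	PC-3p-30485_40	down
LV	miR-7641	up
LV	miR-3074-5p	up
LV	bta-miR-221_R+1	up
LV	bta-miR-148a	down
LV	oar-miR-370-3p_R-2	down
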