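tissue	mirna_id	ave_log_exp	fc	fdr
lung	bta-miR-22-3p_R+1	13.670	2.041	0.022
lung	bta-miR-27a-3p_R+1	10.604	1.700	0.022
lung	miR-210	6.461	0.476	0.022
lung	bta-miR-92a_R+1	13.596	0.644	0.031
lung	hsa-miR-335*	7.163	2.050	0.031
lung	miR-668-3p	2.997	0.388	0.031
lung	hsa-miR-4448_R-3_1ss6CG	1.806	4.750	0.031
lung	bta-miR-181a_R-1	14.572	0.701	0.034
lung	miR-181a	14.570	0.697	0.034
lung	miR-92a-3p	13.138	0.645	0.040
lung	hsa-miR-125b-1*	4.604	2.279	0.040
lung	bta-let-7a-2-p3	12.368	1.285	0.042
lung	bta-miR-146a_R-2	6.930	2.683	0.042
lung	miR-142-3p	4.924	2.738	0.045
lung	bta-miR-504_R+1	5.318	0.482	0.049
lung	PC-3p-30485_40	4.459	0.581	0.055
lung	bta-miR-146b	4.837	3.743	0.056
lung	miR-133	4.962	0.644	0.064
lung	let-7	12.739	1.254	0.069
lung	bta-miR-23a	9.264	1.491	0.069
lung	miR-181a-2-3p	9.014	0.617	0.069
lung	bta-miR-21_R-1	2.287	2.546	0.069
lung	miR-142b	9.234	1.981	0.070
lung	bta-miR-378	9.099	1.536	0.070
lung	miR-222-3p	7.495	1.614	0.070
lung	bta-miR-328	5.540	0.573	0.070
lung	miR-148b-5p	5.242	1.606	0.070
lung	bta-miR-223	4.582	4.969	0.070
lung	miR-1306-5p	3.701	0.595	0.070
lung	hsa-miR-24-2*_L+1R-1	4.957	1.928	0.071
lung	bta-miR-191_R-1	13.630	1.547	0.076
lung	miR-144-3p	4.981	2.021	0.076
lung	miR-323	3.089	0.452	0.076
lung	mmu-miR-503*_L+1R-3_1ss15AG	3.448	0.49	0.085
lung	bta-miR-25	12.341	0.849	0.090
lung	hsa-let-7d*	7.096	0.608	0.090
lung	bta-miR-1343*_L+1R+2	5.993	0.682	0.090
lung	oar-miR-485-5p	5.616	0.657	0.100
lung	bta-miR-30e-5p	11.853	1.47	0.113
lung	miR-192	10.965	1.246	0.113
lung	bta-miR-1468	10.679	1.76	0.113
lung	bta-miR-148b	9.902	1.275	0.113
lung	miR-24	8.570	1.423	0.113
lung	bta-miR-15b	7.059	1.393	0.113
lung	miR-155	6.703	1.409	0.113
lung	bta-miR-424*	6.309	0.668	0.113
lung	miR-1260	3.521	2.076	0.113
lung	bta-miR-96	2.639	0.372	0.113
lung	miR-223-5p	1.765	4.44	0.113
lung	oar-miR-323c	5.590	0.563	0.114
lung	bta-miR-2483*	5.120	0.557	0.123
lung	miR-127	15.017	0.769	0.143
lung	bta-miR-130a	10.981	0.806	0.143
lung	oar-miR-410-3p	9.152	0.7	0.143
lung	bta-miR-363_L+1	4.824	0.572	0.143
lung	miR-3074-5p	9.780	1.386	0.144
lung	bta-miR-7	2.342	1.673	0.144
lung	miR-29a	6.802	1.826	0.149
PA	bta-miR-10a_R-1	14.450	0.221	3E-04
PA	PC-5p-874723_1	2.760	20.32	3E-04
PA	bta-miR-98	11.250	2.025	0.013
PA	bta-miR-490_R+1	3.492	0.2	0.018
PA	hsa-miR-148a*_L+1	8.203	1.887	0.049
PA	hsa-miR-335*	7.915	0.422	0.049
PA	miR-499b-3p	4.513	0.199	0.049
PA	bta-miR-22-3p_R+1	15.100	1.534	0.051
PA	miR-1	5.549	0.471	0.063
PA	hsa-miR-10a*_R-1	3.254	0.192	0.063
PA	miR-210	8.370	0.444	0.073
PA	bta-miR-143_R-1	19.100	0.449	0.102
PA	miR-181a	13.170	0.627	0.113
PA	bta-miR-181a_R-1	13.170	0.629	0.113
PA	miR-409b	9.996	1.768	0.113
PA	miR-296-3p	6.497	1.932	0.113
LV	bta-miR-22-3p_R+1	14.832	2.008	0.058
LV	bta-miR-424	8.196	0.557	0.118
LV	mmu-miR-208a-5p	2.293	20.47	0.118
LV	miR-210	5.913	0.479	0.127
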