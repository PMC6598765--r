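sample_id	protocol	ab_first	bsa	primary	spikein	carryover
pA_lo-hi_1	pA_lo-hi	no	no	5913983	743	3455
pA_lo-hi_2	pA_lo-hi	no	yes	7748003	858	4988
pA_lo-hi_3	pA_lo-hi	yes	no	5202278	2288	16110
pA_lo-hi_4	pA_lo-hi	yes	yes	5178086	1804	18759
pA_std_1	pA_std	no	no	6013347	595	2462
pA_std_2	pA_std	no	yes	6005080	859	2295
pA_std_3	pA_std	yes	no	4104736	2624	21236
pA_std_4	pA_std	yes	yes	3972820	2328	19245
pAG_lo-hi_1	pAG_lo-hi	no	no	6999802	789	404
pAG_lo-hi_2	pAG_lo-hi	no	yes	6374939	642	467
pAG_lo-hi_3	pAG_lo-hi	yes	no	4140407	1565	1291
pAG_lo-hi_4	pAG_lo-hi	yes	yes	4058693	2382	5289
pAG_std_1	pAG_std	no	no	7514127	308	567
pAG_std_2	pAG_std	no	yes	5935592	355	125
pAG_std_3	pAG_std	yes	no	4594153	1271	555
pAG_std_4	pAG_std	yes	yes	5379610	2509	1353
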