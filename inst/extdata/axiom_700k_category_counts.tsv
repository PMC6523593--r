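mode	AAvar	ABvar	BBvar	HHR	CRBT	MHR	NMH	Other	OTV	PHR
ALL_HOM	69	158	182	1	250	334	2216	2820	1772	3040
HIGH_MOD_EFF	385	423	388	4	1432	1647	9401	3986	923	47691
INFPs	5066	7159	5413	102	24764	25718	73117	91597	10802	288798
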