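class	nZeroMendelianErrors
NMH	45344
OTV	152
AAvar	1380
ABvar	2192
BBvar	906
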