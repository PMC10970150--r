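marker	statistic	value
psba_trnh	gst	0.1546
psba_trnh	nst	0.2194
trnl_trnl	gst	0.2531
trnl_trnl	nst	0.6972
psba_trnh	phi_st	0.2655
trnl_trnl	phi_st	0.7004
concatenated	phi_st	0.4284
mtdna	fst	0.8884
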