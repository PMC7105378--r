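host_id	host_timepoint	phage_id	phage_timepoint	score
founderF	0	stock_01	0	1
founderF	0	stock_02	0	1
founderF	0	phage_t24_01	24	1
founderF	0	phage_t24_02	24	0.5
founderF	0	phage_t48_01	48	0.5
founderF	0	phage_t48_02	48	0
colony24_01	24	stock_01	0	1
colony24_01	24	stock_02	0	1
colony24_01	24	phage_t24_01	24	0.5
colony24_01	24	phage_t24_02	24	0.5
colony24_01	24	phage_t48_01	48	0
colony24_01	24	phage_t48_02	48	0.5
colony48_01	48	stock_01	0	1
colony48_01	48	stock_02	0	1
colony48_01	48	phage_t24_01	24	1
colony48_01	48	phage_t24_02	24	1
colony48_01	48	phage_t48_01	48	1
colony48_01	48	phage_t48_02	48	0.5
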