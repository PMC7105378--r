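host_id	dilution_factor	plaques	volume_ml
wildtype_host	1e-04	2000	0.002
wildtype_host	1e-05	197	0.002
wildtype_host	1e-06	22	0.002
wildtype_host	1e-07	2	0.002
wildtype_host	1e-08	0	0.002
spacerF_host	1	0	0.002
spacerF_host	0.1	0	0.002
spacerF_host	0.01	0	0.002
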