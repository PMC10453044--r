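gene_id	sample	stage	tpm
TraesCS6B02G080750	stem_rep1	reproductive	38.5
TraesCS6B02G080750	stem_rep2	reproductive	41.0
TraesCS6B02G080750	leaf_veg1	vegetative	2.1
TraesCS6B02G080700	stem_rep1	reproductive	0.8
TraesCS6B02G080700	stem_rep2	reproductive	1.1
TraesCS6B02G080700	leaf_veg1	vegetative	0.4
TraesCS6B02G080800	stem_rep1	reproductive	5.0
TraesCS6B02G080800	stem_rep2	reproductive	4.6
TraesCS6B02G080800	leaf_veg1	vegetative	0.9
TraesCS6B02G079600	stem_rep1	reproductive	1.6
TraesCS6B02G079600	stem_rep2	reproductive	1.9
TraesCS6B02G079600	leaf_veg1	vegetative	3.2
TraesCS6B02G080100	stem_rep1	reproductive	0.3
TraesCS6B02G080100	stem_rep2	reproductive	0.2
TraesCS6B02G080100	leaf_veg1	vegetative	0.1
SYNB6G000100	stem_rep1	reproductive	0.0
SYNB6G000100	stem_rep2	reproductive	0.1
SYNB6G000100	leaf_veg1	vegetative	0.0
SYNB6G000300	stem_rep1	reproductive	1.2
SYNB6G000300	stem_rep2	reproductive	0.9
SYNB6G000300	leaf_veg1	vegetative	25.0
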