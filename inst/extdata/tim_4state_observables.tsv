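quantity	value	units	source
S_exp	0.31	nats	published_observables/summary
S_opt	0.27	nats	published_observables/summary
S_max	1.39	nats	published_observables/summary
sigma_tot_exp	0.08	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_opt	0.12	kJ.mol-1.K-1.s-1	published_observables/summary
activity_gain_product_release_opt	0.3	fraction	published_observables/summary
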