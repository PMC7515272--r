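quantity	variant	value	units	source
S_exp	PC1	0.68	nats	published_observables/summary
S_exp	RTEM	0.74	nats	published_observables/summary
S_exp	Lac1	0.86	nats	published_observables/summary
S_opt	PC1	0.65	nats	published_observables/summary
S_opt	RTEM	0.54	nats	published_observables/summary
S_opt	Lac1	0.78	nats	published_observables/summary
S_max	PC1	1.1	nats	published_observables/summary
S_max	RTEM	1.1	nats	published_observables/summary
S_max	Lac1	1.1	nats	published_observables/summary
sigma_tot_exp	PC1	5.73	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_exp	RTEM	56.18	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_exp	Lac1	120.76	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_opt	PC1	6.08	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_opt	RTEM	73.67	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_opt	Lac1	161.11	kJ.mol-1.K-1.s-1	published_observables/summary
evolutionary_distance	PC1	1.19	1	published_observables/summary
evolutionary_distance	RTEM	1.44	1	published_observables/summary
evolutionary_distance	Lac1	1.6	1	published_observables/summary
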