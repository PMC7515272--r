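quantity	value	units	source
p_O	0.04	1	published_observables/state_probabilities
p_OATP	0.3	1	published_observables/state_probabilities
p_OADP	0.49	1	published_observables/state_probabilities
p_OP	0.01	1	published_observables/state_probabilities
p_OPADP	0.16	1	published_observables/state_probabilities
sigma_T	3.175	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_M	1.117	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_DM	0.158	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_PM	0.121	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_PE	0.026	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_DE	0.007	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
sigma_tot	4.604	kJ.mol-1.K-1.s-1	published_observables/transition_entropy_production
J_T	81.06	s-1	published_observables/transition_fluxes
J_M	81.06	s-1	published_observables/transition_fluxes
J_DM	72.45	s-1	published_observables/transition_fluxes
J_PM	72.45	s-1	published_observables/transition_fluxes
J_PE	8.62	s-1	published_observables/transition_fluxes
J_DE	8.62	s-1	published_observables/transition_fluxes
eta_opt	0.69	1	published_observables/summary
S_exp	1.17	nats	published_observables/summary
S_opt	1.17	nats	published_observables/summary
S_max	1.61	nats	published_observables/summary
sigma_tot_exp	4.7	kJ.mol-1.K-1.s-1	published_observables/summary
sigma_tot_opt	4.6	kJ.mol-1.K-1.s-1	published_observables/summary
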