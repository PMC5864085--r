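#provenance kind=published_ensemble_summary
#provenance note=per-system self-association ensemble summaries; k in 1e6/s, dG lower bound in kJ/mol
#units t_sim_us=us
#units k=1/us
#units dG_lower_bound=kJ/mol
receptors	membrane	t_sim_us	n_simulations	n_dimers	k	dG_lower_bound
CXCR4/CXCR4	POPC	3	501	251	0.274	-24.95
CXCR4/CXCR4	POPC/30% chol	6	499	129	0.057	-19.84
CCR5/CCR5	POPC	3	506	196	0.190	-18.95
CCR5/CCR5	POPC/30% chol	8	503	190	0.063	-17.19
CCR2/CCR2	POPC	3	507	249	0.239	-19.61
CCR2/CCR2	POPC/30% chol	8	498	212	0.079	-18.71
CXCR4/CCR5	POPC	3	505	274	0.281	-19.92
CXCR4/CCR5	POPC/30% chol	8	511	244	0.084	-19.27
CXCR4/CCR2	POPC	3	505	275	0.302	-20.48
CXCR4/CCR2	POPC/30% chol	8	503	209	0.075	-18.79
CCR5/CCR2	POPC	3	501	216	0.224	-18.84
CCR5/CCR2	POPC/30% chol	8	499	207	0.074	-18.17
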