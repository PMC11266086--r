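exposure	mediator	outcome	beta_c	beta_c_lo	beta_c_hi	beta_a	beta_a_lo	beta_a_hi	beta_b	beta_b_lo	beta_b_hi	indirect_published	indirect_lo	indirect_hi	sobel_p_published	proportion_published	proportion_lo	proportion_hi
IGF-1	BMI	Knee OA	0.067	0.013	0.122	0.038	0.037	0.098	0.663	0.602	0.724	0.025	0.005	0.046	0.016	37.07	7.41	68.20
IGF-1	BMI	Hip OA	0.124	0.063	0.186	0.038	0.037	0.098	0.417	0.342	0.491	0.016	0.003	0.029	0.018	12.86	2.41	23.31
IGF-1	BMI	Spine OA	NA	NA	NA	0.038	0.037	0.098	0.420	0.347	0.493	0.016	0.003	0.030	0.018	NA	NA	NA
IGF-1	BMI	Hand OA	0.084	0.014	0.153	0.038	0.037	0.098	0.1999	0.114	0.285	0.008	0.001	0.015	0.033	9.58	1.20	17.20
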