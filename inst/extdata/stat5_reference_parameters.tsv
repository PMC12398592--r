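parameter	value	b_l	b_u	free
Epo_degradation_BaF3	0.026982514033029	1e-5	1e5	TRUE
k_exp_hetero	1.00067973851508e-05	1e-5	1e5	TRUE
k_exp_homo	0.006170228086381	1e-5	1e5	TRUE
k_imp_hetero	0.0163679184468	1e-5	1e5	TRUE
k_imp_homo	97749.3794024716	1e-5	1e5	TRUE
k_phos	15766.5070195731	1e-5	1e5	TRUE
k_exp_aug_A	0.01	1e-5	1e5	TRUE
k_exp_aug_B	0.01	1e-5	1e5	TRUE
k_exp_aug_AB	0.01	1e-5	1e5	TRUE
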