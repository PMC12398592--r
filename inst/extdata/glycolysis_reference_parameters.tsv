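parameter	value	b_l	b_u	free
J0	2.5	0.25	25	TRUE
k1	100	10	1000	TRUE
k2	6	0.6	60	TRUE
k3	16	1.6	160	TRUE
k4	100	10	1000	TRUE
k5	1.28	0.128	12.8	TRUE
k6	12	1.2	120	TRUE
K1	0.52	0.052	5.2	TRUE
kappa	13	1.3	130	TRUE
phi	0.1	0.01	1	TRUE
k_ex	1.8	0.18	18	TRUE
N	1	0.1	10	TRUE
A	4	0.4	40	FALSE
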