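state	value
S1	1.125
S2	0.95
S3	0.075
S4	0.16
N2	0.265
A3	0.7
S4_ex	0.077
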