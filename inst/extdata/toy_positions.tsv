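neuron_id	class	x_mm	y_mm
HS1	sensory	0.02	0.05
HM1	motor	0.05	0.02
CM1	motor	0.55	0.03
TS1	sensory	1.10	0.04
TI1	inter	1.05	0.06
HI1	inter	0.10	0.04
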