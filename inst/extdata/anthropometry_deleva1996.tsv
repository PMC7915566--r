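segment	mass_fraction	com_fraction	gyration_fraction
foot	0.0137	0.4415	0.257
shank	0.0433	0.4459	0.251
thigh	0.1416	0.4095	0.329
head_arms_trunk	0.6028	0.5000	0.400
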