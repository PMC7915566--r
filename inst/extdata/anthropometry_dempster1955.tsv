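segment	mass_fraction	com_fraction	gyration_fraction
foot	0.0145	0.5000	0.475
shank	0.0465	0.4330	0.302
thigh	0.1000	0.4330	0.323
head_arms_trunk	0.6780	0.5000	0.400
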