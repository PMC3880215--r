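substrate	time_h	acetic_gL	acetic_sd	ethanol_gL	ethanol_sd	glucose_mg_per_g	glucose_sd
switchgrass	0	0.05	0.04	0.02	0.01	522	2
switchgrass	12	0.3	0.09	0.1	0.02	423	41
switchgrass	37	0.5	0.01	0.2	0.001	281	22
populus	0	0.05	0.04	0.03	0.01	584	15
populus	12	0.4	0.01	0.2	0.01	368	13
populus	37	0.8	0.08	0.3	0.03	220	32
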