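gene_id	delta_g_hyb	saturation	intensity_scale	temperature	gas_constant
MNDA	433.97	3105	7.15487245662143	310.15	0.0019872
POU2AF1	473.5	4684	9.89229144667371	310.15	0.0019872
MEF2C	472.81	5110	10.8077240329096	310.15	0.0019872
SMAD3	465.08	4497	9.66930420572805	310.15	0.0019872
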