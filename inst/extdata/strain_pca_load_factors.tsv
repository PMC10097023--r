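# Published load-factor table of the three probiotic indicators for the
# 14-strain screen (values printed to 3 decimals). Characteristic roots
# 2.270 / 0.524; explained variance 75.66% / 17.48%; cumulative 93.137%.
indicator	pc1	pc2
gastrointestinal_tolerance	0.811	0.567
self_cohesive_capacity	0.862	-0.442
hydrophobic_rate	0.932	-0.085
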