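n_proteins = 119
conformer_mu = 6.5999999999999996
conformer_size = 1.1000000000000001
conformer_min = 2
conformer_max = 73
sas_mu = 5.75
sas_size = 1.5
sas_min = 1
disease_fraction = 0.59999999999999998
disease_shift = 0.93000000000000005
disease_shape = 1.2
disease_scale = 2.6400000000000001
disease_stab_weight = 0.12
disease_stab_shift = 1.2
disease_stab_shape = 1.6000000000000001
disease_stab_scale = 1.1000000000000001
neutral_shift = -0.29999999999999999
neutral_shape = 1
neutral_scale = 1.3899999999999999
neutral_stab_weight = 0.070000000000000007
neutral_stab_shift = 0.29999999999999999
neutral_stab_shape = 1.2
neutral_stab_scale = 1
difficulty_max_flip = 0.5
difficulty_exponent = 0.80000000000000004
conformer_sigma = 1
missing_rate = 0
bound_prob = 0.5
seed = 1
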