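n_total	n_female	n_male	carriers_female	carriers_male
17864	7333	10531	125	144
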