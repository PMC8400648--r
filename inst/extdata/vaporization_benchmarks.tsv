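compound	T_K	dHvap_MD	dHvap_MD_sd	dHvap_exp	dHvap_exp_sd
Naproxen	410	108.2	1.0	106.9	3.0
Ibuprofen	410	90.0	NA	84.4	3.0
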