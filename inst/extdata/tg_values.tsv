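compound	Tg_MD_rho	Tg_MD_D	Tg_MD	Tg_exp	dev_printed
Carbamazepine	384	374	379	315	20
Ibuprofen	295	286	290	228	27
Indomethacin	388	388	388	313	24
Naproxen	343	347	345	278	24
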