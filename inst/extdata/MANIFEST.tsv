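file	md5
densities.tsv	500c2175e1d016d9a14e1a3db916c539
fusion_enthalpies.tsv	f1d766a6c7d2579e4239d067b4ed9c7b
tg_values.tsv	7f4154265adbcde2ed94359ec6c92473
vaporization_benchmarks.tsv	eab8dcf1a792f2f2e28ded121c52f3e0
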