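# Reported codon site-model fits (codeml) for the wasp double-domain OBP
# expansion: reported log-likelihoods, reported likelihood-ratio
# statistics and degrees of freedom. The M8a-vs-M8 row did not report df;
# df = 2 is recorded here because only df = 2 reproduces the reported
# p-value (exp(-7.58/2) ~= 0.023), and the row is flagged by lrt_table()
# because the reported statistics are not always equal to 2*(lnL_alt -
# lnL_null).
model_null	model_alt	lnL_null	lnL_alt	statistic	df	df_source	p_printed
M1a	M2a	-7077.78	-7077.07	0.71	2	reported	0.7
M7	M8	-7057.53	-7051.00	11.07	2	reported	0.004
M8a	M8	-7055.78	-7051.00	7.58	2	assumed	0.02
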