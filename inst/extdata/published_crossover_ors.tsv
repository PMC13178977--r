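score	exposure	or11	or10	or01	n_analyzed
unweighted	sleep	1.70	1.40	1.16	2314
unweighted	physical_activity	1.59	1.83	1.16	2321
weighted	sleep	1.51	1.07	1.07	2314
weighted	physical_activity	1.52	1.77	1.20	2321
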