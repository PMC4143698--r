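region	all	common	rare	very_rare
all	49839	11414	6611	31814
genic	16790	2949	4763	9078
flanking	33049	8465	1848	22736
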