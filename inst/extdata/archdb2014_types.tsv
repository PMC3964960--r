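type	description	total	ds_classified	mcl_classified
BK	beta-link	28418	11777	6054
BN	beta-hairpin	35616	27995	22536
EG	beta-helix310	18349	6950	8531
EH	beta-alpha	42442	23364	19661
GE	helix310-beta	16478	6829	7731
GG	helix310-helix310	3498	704	23
GH	helix310-alpha	16249	7537	10141
HE	alpha-beta	42079	24870	23327
HG	alpha-helix310	14472	5689	9133
HH	alpha-alpha	35294	18200	19503
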