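item	amount_zar
4 Community Health Workers	240000
1 Program Coordinator	400000
Trainer salary	5000
Room & equipment rental	500
Cell phone & airtime	5000
Stationary	3000
Pamphlets	2500
Local transport	8320
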