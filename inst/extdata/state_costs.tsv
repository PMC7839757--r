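state	central	low	high
nonadherent	16340	13889	18790
adherent	8681	7378	9983
remission	0	0	0
death	0	0	0
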