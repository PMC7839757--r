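state	item	central	low	high
nonadherent	Anti-epileptic drugs	0	0	0
nonadherent	Out-patient clinic visits	650	553	748
nonadherent	Out-patient hospital visits	334	284	384
nonadherent	In-patient hospital stays (incl. ambulance)	4533	3853	5213
nonadherent	Lost productivity	10823	9199	12446
adherent	Anti-epileptic drugs	880	748	1012
adherent	Out-patient clinic visits	1300	1105	1495
adherent	Out-patient hospital visits	334	284	384
adherent	In-patient hospital stays (incl. ambulance)	2267	1927	2606
adherent	Lost productivity	3900	3315	4485
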