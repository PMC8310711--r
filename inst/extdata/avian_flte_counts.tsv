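species	group	line_dna	rt	ltrhd
Calypte_anna	autosome	1	171	302
Calypte_anna	Z	0	71	63
Calypte_anna	W	1	503	671
Calypte_anna	male_2n	2	484	730
Calypte_anna	female_2n	5	916	1338
Dromaius_novaehollandiae	autosome	9	129	261
Dromaius_novaehollandiae	Z	2	0	32
Dromaius_novaehollandiae	W	20	1	111
Dromaius_novaehollandiae	male_2n	22	258	586
Dromaius_novaehollandiae	female_2n	40	259	665
Gallus_gallus	autosome	7	392	232
Gallus_gallus	Z	0	74	68
Gallus_gallus	W	17	244	246
Gallus_gallus	male_2n	14	932	600
Gallus_gallus	female_2n	31	1102	778
Lycocorax_pyrrhopterus	autosome	1	396	558
Lycocorax_pyrrhopterus	Z	0	83	88
Lycocorax_pyrrhopterus	W	0	439	678
Lycocorax_pyrrhopterus	male_2n	2	958	1292
Lycocorax_pyrrhopterus	female_2n	4	1314	1882
Strigops_habroptila	autosome	7	354	911
Strigops_habroptila	Z	0	102	225
Strigops_habroptila	W	1	458	871
Strigops_habroptila	male_2n	14	912	2272
Strigops_habroptila	female_2n	29	1268	2918
Taeniopygia_guttata	autosome	0	298	552
Taeniopygia_guttata	Z	0	149	184
Taeniopygia_guttata	W	0	450	723
Taeniopygia_guttata	male_2n	0	894	1472
Taeniopygia_guttata	female_2n	0	1195	2011
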