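species	ti_ltrhd	ti_rt
Calypte_anna	0.834699454	0.895061728
Dromaius_novaehollandiae	0.159539474	0.067857143
Gallus_gallus	0.317589577	0.197674419
Lycocorax_pyrrhopterus	0.457496136	0.372916667
Strigops_habroptila	0.289151356	0.400647948
Taeniopygia_guttata	0.366168478	0.336689038
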