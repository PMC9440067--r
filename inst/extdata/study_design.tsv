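quantity	group	count
samples_analysed	sponge	931
samples_analysed	seawater	355
samples_analysed	sediment	108
species	Demospongiae	110
species	Hexactinellida	56
species	Calcarea	2
species	Homoscleromorpha	1
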