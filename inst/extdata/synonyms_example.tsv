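synonym	canonical	compound_id	molecular_weight
3-methyl-1-butanol	3-methyl-1-butanol	31260	88.15
isoamyl alcohol	3-methyl-1-butanol	31260	88.15
isopentyl alcohol	3-methyl-1-butanol	31260	88.15
isopentanol	3-methyl-1-butanol	31260	88.15
1-octen-3-ol	1-octen-3-ol	18827	128.21
oct-1-en-3-ol	1-octen-3-ol	18827	128.21
lactic acid	lactic acid	612	90.08
2-hydroxypropanoic acid	lactic acid	612	90.08
benzaldehyde	benzaldehyde	240	106.12
phenylmethanal	benzaldehyde	240	106.12
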