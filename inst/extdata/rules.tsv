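ta_type	variant	toxin_molecule	antitoxin_molecule	strand	dmin	dmax
I	I	protein	rna	opposite	-Inf	200
II	II	protein	protein	same	-20	150
III	III	protein	rna	same	-20	150
IV	IV	protein	protein	same	-20	150
V	V	protein	protein	same	-20	150
VI	VI	protein	protein	same	-20	150
VII	VII	protein	protein	same	-20	150
VIII	VIII-creTA	rna	rna	either	-Inf	200
VIII	VIII-sdsr	rna	rna	opposite	-Inf	-1
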