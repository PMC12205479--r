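# Canonical ortholog groups for the Arabidopsis/tomato circuit comparison.
# NLP6/NLP7 and the tomato NLP7A/NLP7B pair collapse to one NLP group (the
# tomato genes cannot be assigned one-to-one to NLP6 vs NLP7); the two
# tomato nitrite reductase genes collapse to NIR. ANAC032 has no clear
# tomato ortholog and therefore no Sl entry.
species	gene	group
At	AtARF18	ARF18
At	AtARF9	ARF9
At	AtANAC032	ANAC032
At	AtDREB26	DREB26
At	AtNLP6	NLP
At	AtNLP7	NLP
At	AtNIR1	NIR
Sl	SlARF18	ARF18
Sl	SlARF9B	ARF9
Sl	SlDREB26	DREB26
Sl	SlNLP7A	NLP
Sl	SlNLP7B	NLP
Sl	SlNIR1	NIR
Sl	SlNIR2	NIR
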