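# Arabidopsis enhanced yeast one-hybrid (eY1H) binding network upstream of
# NLP6/NLP7/NIR1. Binding evidence only: signs and regulatory modes unknown.
# The sub-circuit contains four interconnected three-node feedforward loops
# (ARF9/DREB26/ANAC032, ARF18/DREB26/ANAC032, ARF9/NLP6/NIR1,
# DREB26/ANAC032/NLP7) and one autoregulatory loop (DREB26).
source	target	sign	mode	evidence	species	citation
AtARF9	AtANAC032	unknown	unknown	eY1H	At	core
AtARF9	AtDREB26	unknown	unknown	eY1H	At	core
AtARF9	AtNLP6	unknown	unknown	eY1H	At	core
AtARF9	AtNIR1	unknown	unknown	eY1H	At	core
AtARF18	AtANAC032	unknown	unknown	eY1H	At	core
AtARF18	AtDREB26	unknown	unknown	eY1H	At	core
AtDREB26	AtANAC032	unknown	unknown	eY1H	At	core
AtDREB26	AtNLP7	unknown	unknown	eY1H	At	core
AtDREB26	AtDREB26	unknown	unknown	eY1H	At	core
AtANAC032	AtNLP7	unknown	unknown	eY1H	At	core
AtNLP6	AtNIR1	unknown	unknown	eY1H	At	core
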