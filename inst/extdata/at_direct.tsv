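# Arabidopsis direct regulatory network around NLP6/NLP7 and NIR1.
# citation=core: the eight direct, regulatory interactions retained after the
#   protoplast assays (modified TARGET and/or promoter-luciferase
#   transactivation) reduced the 29 candidate binding interactions to 8.
# citation=supplementary: the AtARF9 -| AtDREB26 repression supported by
#   supplementary transactivation data (AtARF9 protein could not be purified
#   for the in vitro binding assays).
# citation=inference: indirect repression of the NLP/NIR1 tier by AtDREB26
#   inferred from reporter assays; mode=indirect, excluded from the direct
#   layer used for knockout prediction and conservation.
source	target	sign	mode	evidence	species	citation
AtARF18	AtANAC032	repressing	direct	target_direct	At	core
AtARF18	AtDREB26	repressing	direct	transactivation	At	core
AtNLP6	AtDREB26	activating	direct	transactivation	At	core
AtNLP7	AtDREB26	activating	direct	transactivation	At	core
AtANAC032	AtNLP7	repressing	direct	target_direct	At	core
AtANAC032	AtNIR1	repressing	direct	target_direct	At	core
AtNLP6	AtNIR1	activating	direct	target_direct	At	core
AtNLP7	AtNIR1	activating	direct	target_direct	At	core
AtARF9	AtDREB26	repressing	direct	transactivation	At	supplementary
AtDREB26	AtNLP6	repressing	indirect	target_indirect	At	inference
AtDREB26	AtNLP7	repressing	indirect	target_indirect	At	inference
AtDREB26	AtNIR1	repressing	indirect	target_indirect	At	inference
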