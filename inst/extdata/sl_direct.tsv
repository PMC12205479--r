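# Tomato direct regulatory network (hairy-root protoplast TARGET assays).
# citation=core: the five interactions confirmed as direct and regulatory.
# citation=inference: indirect repression of the SlNLP7 genes by SlARF18
#   (binding observed in vitro but not reflected as direct regulation).
source	target	sign	mode	evidence	species	citation
SlARF18	SlDREB26	repressing	direct	target_direct	Sl	core
SlARF9B	SlDREB26	repressing	direct	target_direct	Sl	core
SlDREB26	SlNLP7B	repressing	direct	target_direct	Sl	core
SlNLP7A	SlNIR1	activating	direct	target_direct	Sl	core
SlNLP7B	SlNIR1	activating	direct	target_direct	Sl	core
SlARF18	SlNLP7A	repressing	indirect	target_indirect	Sl	inference
SlARF18	SlNLP7B	repressing	indirect	target_indirect	Sl	inference
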