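# Arabidopsis in vitro protein-DNA binding network (plate-based binding of
# purified TFs to candidate-site probes). Binding evidence only: signs and
# regulatory modes unknown. AtARF9 protein could not be purified, so it
# contributes no edges here.
# Count caveat: the study's Results tally these as 28 TF-DNA interactions
# while its Discussion cites 29 interactions via 46 cis-elements; the 23
# edges below are those recoverable from the Results text, and the
# discrepancy between the three printed counts is left unresolved here.
# Autoregulation caveat: "3 instances of potential autoregulation" are
# reported for a list of FOUR genes (ANAC032, ARF18, DREB26, NLP6); all four
# self-edges are included and the ambiguity is noted.
source	target	sign	mode	evidence	species	citation
AtNLP6	AtNIR1	unknown	unknown	in_vitro	At	core
AtNLP7	AtNIR1	unknown	unknown	in_vitro	At	core
AtNLP7	AtNLP7	unknown	unknown	in_vitro	At	core
AtARF18	AtANAC032	unknown	unknown	in_vitro	At	core
AtARF18	AtDREB26	unknown	unknown	in_vitro	At	core
AtANAC032	AtNLP7	unknown	unknown	in_vitro	At	core
AtDREB26	AtNIR1	unknown	unknown	in_vitro	At	core
AtNLP6	AtARF18	unknown	unknown	in_vitro	At	core
AtNLP6	AtDREB26	unknown	unknown	in_vitro	At	core
AtNLP7	AtARF18	unknown	unknown	in_vitro	At	core
AtNLP7	AtDREB26	unknown	unknown	in_vitro	At	core
AtANAC032	AtDREB26	unknown	unknown	in_vitro	At	core
AtARF18	AtNIR1	unknown	unknown	in_vitro	At	core
AtANAC032	AtNIR1	unknown	unknown	in_vitro	At	core
AtDREB26	AtNLP6	unknown	unknown	in_vitro	At	core
AtANAC032	AtNLP6	unknown	unknown	in_vitro	At	core
AtANAC032	AtANAC032	unknown	unknown	in_vitro	At	ambiguous_autoregulation
AtARF18	AtARF18	unknown	unknown	in_vitro	At	ambiguous_autoregulation
AtDREB26	AtDREB26	unknown	unknown	in_vitro	At	ambiguous_autoregulation
AtNLP6	AtNLP6	unknown	unknown	in_vitro	At	ambiguous_autoregulation
AtNLP6	AtNLP7	unknown	unknown	in_vitro	At	core
AtNLP7	AtNLP6	unknown	unknown	in_vitro	At	core
AtDREB26	AtNLP7	unknown	unknown	in_vitro	At	core
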