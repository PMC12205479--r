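# Arabidopsis reporter-assay genotypes with the qualitative reporter
# direction observed vs wild type (protoplast nitrate-responsive reporter at
# 0/1/10 mM KNO3). knocked_out is comma-separated.
# Note: the single arf9 and dreb26 mutants showed reduced reporter
# sensitivity, but neither gene reaches NIR1 through the direct layer, so
# their predictions are "unconnected" and the comparisons untestable.
label	knocked_out	observed_direction
Atanac032	AtANAC032	higher
Atarf9	AtARF9	lower
Atarf18	AtARF18	lower
Atdreb26	AtDREB26	lower
Atnlp6	AtNLP6	lower
Atnlp7	AtNLP7	lower
Atarf18_anac032	AtARF18,AtANAC032	higher
Atanac032_nlp7	AtANAC032,AtNLP7	lower
Atdreb26_nlp7	AtDREB26,AtNLP7	lower
Atarf18_nlp7	AtARF18,AtNLP7	lower
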