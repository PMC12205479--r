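# Tomato reporter-assay genotypes (hairy-root protoplasts) with the
# qualitative reporter direction observed vs wild type at 0/1/10 mM KNO3.
label	knocked_out	observed_direction
Slarf9b	SlARF9B	lower
Slarf18	SlARF18	lower
Sldreb26	SlDREB26	higher
Slnlp7a	SlNLP7A	lower
Slnlp7b	SlNLP7B	lower
Slarf9b_18	SlARF9B,SlARF18	lower
Slarf9b_18_dreb26	SlARF9B,SlARF18,SlDREB26	higher
Slnlp7a_7b	SlNLP7A,SlNLP7B	lower
Sldreb26_nlp7a_7b	SlDREB26,SlNLP7A,SlNLP7B	lower
Slarf9b_18_dreb26_nlp7a_7b	SlARF9B,SlARF18,SlDREB26,SlNLP7A,SlNLP7B	lower
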