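peptide_sequence	spike_amount	sample_conversion	dilution_1	dilution_2	dilution_3	dilution_4	dilution_5	dilution_6	dilution_7	dilution_8	dilution_9
SSEDPNEDIVER	1	2	8	4	2	1	0.5	0.25	0.12	0.06	0.03
AGDFLEANYMNLQR	2	2	8	4	2	1	0.5	0.25	0.12	0.06	0.03
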