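patient_id	sample_id	timepoint
P001	P001_B	baseline
P001	P001_F	followup
P002	P002_B	baseline
P002	P002_F	followup
P003	P003_B	baseline
P003	P003_F	followup
P004	P004_B	baseline
P004	P004_F	followup
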