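term_id	term_name	accession	evidence_code
GO:0000001	process_1	SP00008	IMP
GO:0000001	process_1	SP00002	IMP
GO:0000001	process_1	SP00003	IDA
GO:0000001	process_1	SP00007	IDA
GO:0000001	process_1	SP00004	IDA
GO:0000001	process_1	SP00001	EXP
GO:0000001	process_1	SP00005	IDA
GO:0000001	process_1	SP00006	EXP
GO:0000002	process_2	SP00008	EXP
GO:0000002	process_2	SP00006	EXP
GO:0000002	process_2	SP00007	IEA
GO:0000002	process_2	SP00002	IEA
GO:0000002	process_2	SP00005	IMP
GO:0000002	process_2	SP00001	EXP
GO:0000002	process_2	SP00004	IMP
GO:0000002	process_2	SP00003	IMP
GO:0000003	process_3	SP00002	IDA
GO:0000003	process_3	SP00006	IMP
GO:0000003	process_3	SP00001	IDA
GO:0000003	process_3	SP00008	IEA
GO:0000003	process_3	SP00005	IMP
GO:0000003	process_3	SP00004	EXP
GO:0000003	process_3	SP00007	IEA
GO:0000003	process_3	SP00003	IMP
GO:0000004	process_4	SP00008	IEA
GO:0000004	process_4	SP00002	IMP
GO:0000004	process_4	SP00007	EXP
GO:0000004	process_4	SP00004	IMP
GO:0000004	process_4	SP00006	IEA
GO:0000004	process_4	SP00001	IDA
GO:0000004	process_4	SP00005	IEA
GO:0000004	process_4	SP00003	IMP
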