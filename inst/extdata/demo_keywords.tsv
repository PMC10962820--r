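accession	keyword
SP00001	KW-1280
SP00002	KW-1280
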