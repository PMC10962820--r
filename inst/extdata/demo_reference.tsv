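accession	direction
SP00001	down
SP00002	down
SP00003	up
SP00004	unchanged
SP00005	up
SP00006	down
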