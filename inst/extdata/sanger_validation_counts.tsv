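wes_call	sanger_hom_ref	sanger_het	sanger_hom_alt
hom_ref	177	1	0
het	9	141	7
hom_alt	0	3	38
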