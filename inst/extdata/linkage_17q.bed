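chr17	34355566	52135011	locus
chr17	54612055	61596548	locus
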