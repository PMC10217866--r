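# SYNTHETIC STAND-IN morpheme set.
# Illustrative CpG-rich hexamers of the kind recognised by the MLL1/MLL2
# CXXC domain; NOT the published morpheme list. Replace with the
# published words (morpheme_file config key) for real analyses.
M1	CGCCGC
M2	CCGCGC
M3	CGCGCA
M4	GCGCGC
M5	ACGCGC
M6	CGCGCG
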