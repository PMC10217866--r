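# SYNTHETIC STAND-IN list of ZFBS-morph overlap words.
# Generated with overlap_motifs(default_zfbs(), default_morphemes(),
#   min_overlap = 2) from the synthetic morpheme stand-ins; NOT the
# published overlap list. Replace via the overlap_file config key for
# real analyses. Format: id<TAB>word. Complements are added at run time.
OV01	TGCCGCCGC
OV02	TGCCGCGC
OV03	TGCCGCGCA
OV04	TGCCGCGCG
OV05	TGCCGCGCGC
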