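# ZFP57 binding site: the unmethylated hexamer (complement added at run
# time by add_complements()).
ZFBS	TGCCGC
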