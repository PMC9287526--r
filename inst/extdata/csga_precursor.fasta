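>CsgA Escherichia coli major curlin subunit precursor (signal 1-20, mature 21-end)
MKLLKVAAIAAIVFSGSALAGVVPQYGGGGNHGGGGNNSGPNSELNIYQYGGGNSALALQ
TDARNSDLTITQHGGGNGADVGQGSDDSSIDLTQRGFGNSALDQWNGKNSEMTVKQFGGG
NGAAVDQTASNSSVNVTQVGFGNNATAHQY
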