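v_call	j_call	junction	duplicate_count
TRBV5-1*01	TRBJ2-7*01	TGTGCCAGCAGCTTT	120
TRBV5-1*01	TRBJ2-1*01	TGCGCCAGCAGCTTT	30
TRBV7-2	TRBJ2-7	TGTGCCTGGAGCTTT	80
TRBV19	TRBJ1-1	TGTGCCAGCACCTTT	40
TRBV20-1	TRBJ2-3	TGTGCCAAAAGCTTT	25
TRBV9	TRBJ2-5	TGTTAAAGCTTT	5
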