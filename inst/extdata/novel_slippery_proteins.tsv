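sequence_id	pre_codon	stop_codon	unique_peptides
CUFF.26295.1	UUU	UAG	16
CUFF.26296.1	UUU	UAG	15
CUFF.8736.1	UUU	UAA	14
CUFF.25615.1	UUU	UAA	3
CUFF.1984.1	UUU	UAA	1
CUFF.21695.1	AUU	UAA	4
CUFF.2970.1	AUU	UAA	1
CUFF.28108.1	AUU	UAG	1
CUFF.4268.1	AAG	UAA	1
CUFF.166.1	ACC	UAA	11
CUFF.13288.1	AGA	UAG	2
CUFF.16329.1	UAU	UAG	3
CUFF.9615.1	CUU	UAA	1
CUFF.2860.1	AAU	UAA	1
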