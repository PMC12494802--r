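TF	Target_Gene	Regulation	PMID
AHR	IL13	Unknown	22981205
AHR	IL1B	Unknown	23349129
AHR	IL6	Activation	20511231
AHR	IL6	Unknown	18483242; 23349129
AIP	NFKB2	Repression	21984905
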