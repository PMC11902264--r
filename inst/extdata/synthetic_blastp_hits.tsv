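subject	queryCover	identity	evalue
SYN_HIT_000001.1	100	87.50	2e-05
SYN_HIT_000002.1	93	86.67	8e-04
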