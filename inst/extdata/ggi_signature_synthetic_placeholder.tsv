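gene_id	direction
SYN_UP_01	up
SYN_UP_02	up
SYN_UP_03	up
SYN_UP_04	up
SYN_DOWN_01	down
SYN_DOWN_02	down
SYN_DOWN_03	down
SYN_DOWN_04	down
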