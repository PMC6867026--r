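#n=12
A	(2 4)(3 9)(6 8)(10 11)
B	(2 7)(3 8)(4 5)(6 9)(10 11)
C	(2 3)(4 5)(6 7)(8 9)(10 11)
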