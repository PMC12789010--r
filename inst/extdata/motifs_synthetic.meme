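MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF PRDM1LIKE prdm1_like_synthetic
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
 0.97 0.01 0.01 0.01
 0.97 0.01 0.01 0.01
 0.97 0.01 0.01 0.01
 0.01 0.01 0.97 0.01
 0.01 0.01 0.01 0.97
 0.01 0.01 0.97 0.01
 0.97 0.01 0.01 0.01
 0.97 0.01 0.01 0.01
 0.97 0.01 0.01 0.01
 0.01 0.01 0.97 0.01
 0.01 0.01 0.01 0.97

MOTIF RUNXLIKE runx_like_synthetic
letter-probability matrix: alength= 4 w= 8 nsites= 100 E= 0
 0.01 0.01 0.01 0.97
 0.01 0.01 0.97 0.01
 0.01 0.01 0.01 0.97
 0.01 0.01 0.97 0.01
 0.01 0.01 0.97 0.01
 0.01 0.01 0.01 0.97
 0.01 0.01 0.01 0.97
 0.01 0.01 0.01 0.97
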