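MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF ACT1
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
0.010000  0.010000  0.010000  0.970000
0.010000  0.010000  0.970000  0.010000
0.970000  0.010000  0.010000  0.010000
0.010000  0.970000  0.010000  0.010000
0.010000  0.010000  0.010000  0.970000
0.010000  0.970000  0.010000  0.010000
0.970000  0.010000  0.010000  0.010000

MOTIF REP1
letter-probability matrix: alength= 4 w= 11 nsites= 20 E= 0
0.010000  0.010000  0.970000  0.010000
0.010000  0.010000  0.970000  0.010000
0.010000  0.010000  0.010000  0.970000
0.010000  0.010000  0.970000  0.010000
0.970000  0.010000  0.010000  0.010000
0.010000  0.970000  0.010000  0.010000
0.010000  0.010000  0.010000  0.970000
0.010000  0.970000  0.010000  0.010000
0.970000  0.010000  0.010000  0.010000
0.010000  0.970000  0.010000  0.010000
0.010000  0.970000  0.010000  0.010000

MOTIF EBOX
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.016667  0.950000  0.016667  0.016667
0.950000  0.016667  0.016667  0.016667
0.016667  0.950000  0.016667  0.016667
0.016667  0.016667  0.950000  0.016667
0.016667  0.016667  0.016667  0.950000
0.016667  0.016667  0.950000  0.016667

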