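# Synthetic linear control motif: x1 holds its state and drives x2 drives x3.
# Small driver-analysis motif in the style of Gates & Rocha (2016).
.v 3
.l 1 x1
.l 2 x2
.l 3 x3
.n 1 1 1
0 0
1 1
.n 2 1 1
0 0
1 1
.n 3 1 2
0 0
1 1
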