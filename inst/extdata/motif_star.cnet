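# Synthetic out-star motif: a self-sustaining hub copied by three leaves.
# Small driver-analysis motif in the style of Gates & Rocha (2016).
.v 4
.l 1 hub
.l 2 leaf1
.l 3 leaf2
.l 4 leaf3
.n 1 1 1
0 0
1 1
.n 2 1 1
0 0
1 1
.n 3 1 1
0 0
1 1
.n 4 1 1
0 0
1 1
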