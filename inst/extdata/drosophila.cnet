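# Drosophila melanogaster segment polarity GRN, simplified single-cell
# variant. Transcribed from Albert & Othmer (2003) J Theor Biol 223:1-18.
.v 17
.l 1 SLP
.l 2 wg
.l 3 WG
.l 4 en
.l 5 EN
.l 6 hh
.l 7 HH
.l 8 ptc
.l 9 PTC
.l 10 PH
.l 11 SMO
.l 12 ci
.l 13 CI
.l 14 CIA
.l 15 CIR
.l 16 nhhnHH
.l 17 nWG
.n 1 1 1
0 0
1 1
.n 2 4 1 2 14 15
0000 0
0001 0
0010 0
0011 0
0100 0
0101 0
0110 1
0111 0
1000 0
1001 0
1010 1
1011 0
1100 1
1101 0
1110 1
1111 0
.n 3 1 2
0 0
1 1
.n 4 2 1 17
00 0
01 1
10 0
11 0
.n 5 1 4
0 0
1 1
.n 6 2 5 15
00 0
01 0
10 1
11 0
.n 7 1 6
0 0
1 1
.n 8 3 5 14 15
000 0
001 0
010 1
011 0
100 0
101 0
110 0
111 0
.n 9 3 8 9 16
000 0
001 0
010 1
011 0
100 1
101 1
110 1
111 1
.n 10 2 9 16
00 0
01 0
10 0
11 1
.n 11 2 9 16
00 1
01 1
10 0
11 1
.n 12 1 5
0 1
1 0
.n 13 1 12
0 0
1 1
.n 14 3 9 13 16
000 0
001 0
010 1
011 1
100 0
101 0
110 0
111 1
.n 15 3 9 13 16
000 0
001 0
010 0
011 0
100 0
101 0
110 1
111 0
.n 16 1 16
0 0
1 1
.n 17 1 17
0 0
1 1
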