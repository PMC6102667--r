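# Budding yeast cell-cycle regulatory network (12 nodes).
# Transcribed from Li et al. (2004) PNAS 101:4781-4786.
.v 12
.l 1 CellSize
.l 2 Cln3
.l 3 SBF
.l 4 MBF
.l 5 Cln1,2
.l 6 Sic1
.l 7 Clb5,6
.l 8 Cdh1
.l 9 Clb1,2
.l 10 Mcm1/SFF
.l 11 Cdc20/14
.l 12 Swi5
.n 1 1 1
0 0
1 1
.n 2 1 1
0 0
1 1
.n 3 3 2 3 9
000 0
001 0
010 1
011 0
100 1
101 0
110 1
111 1
.n 4 3 2 4 9
000 0
001 0
010 1
011 0
100 1
101 0
110 1
111 1
.n 5 1 3
0 0
1 1
.n 6 6 5 6 7 9 11 12
000000 0
000001 1
000010 1
000011 1
000100 0
000101 0
000110 0
000111 1
001000 0
001001 0
001010 0
001011 1
001100 0
001101 0
001110 0
001111 0
010000 1
010001 1
010010 1
010011 1
010100 0
010101 1
010110 1
010111 1
011000 0
011001 1
011010 1
011011 1
011100 0
011101 0
011110 0
011111 1
100000 0
100001 0
100010 0
100011 1
100100 0
100101 0
100110 0
100111 0
101000 0
101001 0
101010 0
101011 0
101100 0
101101 0
101110 0
101111 0
110000 0
110001 1
110010 1
110011 1
110100 0
110101 0
110110 0
110111 1
111000 0
111001 0
111010 0
111011 1
111100 0
111101 0
111110 0
111111 0
.n 7 4 4 6 7 11
0000 0
0001 0
0010 1
0011 0
0100 0
0101 0
0110 0
0111 0
1000 1
1001 0
1010 1
1011 1
1100 0
1101 0
1110 1
1111 0
.n 8 5 5 7 8 9 11
00000 0
00001 1
00010 0
00011 0
00100 1
00101 1
00110 0
00111 1
01000 0
01001 0
01010 0
01011 0
01100 0
01101 1
01110 0
01111 0
10000 0
10001 0
10010 0
10011 0
10100 0
10101 1
10110 0
10111 0
11000 0
11001 0
11010 0
11011 0
11100 0
11101 0
11110 0
11111 0
.n 9 6 6 7 8 9 10 11
000000 0
000001 0
000010 1
000011 0
000100 1
000101 0
000110 1
000111 1
001000 0
001001 0
001010 0
001011 0
001100 0
001101 0
001110 1
001111 0
010000 1
010001 0
010010 1
010011 1
010100 1
010101 1
010110 1
010111 1
011000 0
011001 0
011010 1
011011 0
011100 1
011101 0
011110 1
011111 1
100000 0
100001 0
100010 0
100011 0
100100 0
100101 0
100110 1
100111 0
101000 0
101001 0
101010 0
101011 0
101100 0
101101 0
101110 0
101111 0
110000 0
110001 0
110010 1
110011 0
110100 1
110101 0
110110 1
110111 1
111000 0
111001 0
111010 0
111011 0
111100 0
111101 0
111110 1
111111 0
.n 10 2 7 9
00 0
01 1
10 1
11 1
.n 11 2 9 10
00 0
01 1
10 1
11 1
.n 12 4 9 10 11 12
0000 0
0001 0
0010 1
0011 1
0100 1
0101 1
0110 1
0111 1
1000 0
1001 0
1010 0
1011 0
1100 0
1101 0
1110 1
1111 1
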