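# synthetic example chip table in the WCS coordinate-file layout:
# chip_id  lightness_row  hue_col  L*  a*  b*  (all values invented)
1	B	1	25	45	0
2	B	11	25	0	45
3	C	1	45	52	0
4	C	11	45	0	52
5	D	1	65	48	0
6	D	11	65	0	48
7	A	0	15	0	0
8	A	0	50	0	0
9	A	0	75	0	0
10	A	0	95	0	0
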