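# synthetic example term table in the WCS layout:
# language_id  speaker_id  chip_id  term  (all judgments invented)
# language L2 leaves chip 10 with a single judgment and is excluded by
# the sparse-language filter
L1	s1	1	red
L1	s2	1	red
L1	s1	2	blue
L1	s2	2	blue
L1	s1	3	red
L1	s2	3	pink
L1	s1	4	blue
L1	s2	4	blue
L1	s1	5	pink
L1	s2	5	pink
L1	s1	6	blue
L1	s2	6	blue
L1	s1	7	dark
L1	s2	7	dark
L1	s1	8	gray
L1	s2	8	gray
L1	s1	9	gray
L1	s2	9	light
L1	s1	10	light
L1	s2	10	light
L2	t1	1	kale
L2	t2	1	kale
L2	t1	2	buru
L2	t2	2	buru
L2	t1	3	kale
L2	t2	3	kale
L2	t1	4	buru
L2	t2	4	buru
L2	t1	5	kale
L2	t2	5	kale
L2	t1	6	buru
L2	t2	6	buru
L2	t1	7	sefu
L2	t2	7	sefu
L2	t1	8	sefu
L2	t2	8	sefu
L2	t1	9	sefu
L2	t2	9	sefu
L2	t1	10	sefu
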