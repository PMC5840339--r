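1	10000000	10150000	PANGENE01
1	55000000	55120000	PANGENE02
2	20000000	20100000	PANGENE03
3	41000000	41200000	PANGENE04
5	1250000	1400000	PANGENE05
7	55080000	55280000	PANGENE06
9	21960000	22010000	PANGENE07
12	25350000	25420000	PANGENE08
17	7560000	7600000	PANGENE09
17	41190000	41280000	PANGENE10
19	1200000	1230000	PANGENE11
22	23520000	23660000	PANGENE12
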