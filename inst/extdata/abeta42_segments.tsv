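protein	start	end	source	threshold
abeta42	12	21	experimental_lb4	40
abeta42	31	42	experimental_lb4	40
abeta42	13	23	experimental_lb1	55
abeta42	29	42	experimental_lb1	55
abeta42	15	21	zyggregator	1
abeta42	31	42	zyggregator	1
abeta42	17	22	aggrescan	0
abeta42	29	42	aggrescan	0
abeta42	16	22	tango	0
abeta42	29	41	tango	0
abeta42	15	23	waltz	75
abeta42	26	42	waltz	75
abeta42	12	42	pasta	5
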