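protein	start	end	source	threshold
asyn	39	43	experimental_lb4	60
asyn	50	56	experimental_lb4	60
asyn	60	79	experimental_lb4	60
asyn	88	89	experimental_lb4	60
asyn	40	43	experimental_lb1	70
asyn	48	56	experimental_lb1	70
asyn	61	80	experimental_lb1	70
asyn	88	90	experimental_lb1	70
asyn	38	39	zyggregator	1
asyn	50	53	zyggregator	1
asyn	65	76	zyggregator	1
asyn	87	92	zyggregator	1
asyn	1	7	aggrescan	0
asyn	14	19	aggrescan	0
asyn	36	42	aggrescan	0
asyn	49	55	aggrescan	0
asyn	66	77	aggrescan	0
asyn	87	94	aggrescan	0
asyn	14	19	tango	0
asyn	36	42	tango	0
asyn	51	56	tango	0
asyn	62	79	tango	0
asyn	88	95	tango	0
asyn	35	41	waltz	75
asyn	50	55	waltz	75
asyn	68	82	waltz	75
asyn	84	94	waltz	75
asyn	37	40	pasta	5
asyn	47	56	pasta	5
asyn	62	82	pasta	5
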