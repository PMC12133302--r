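entry_id	n_molecules
2beg	1
2lmq	3
8bfa	1
5kk3	2
8azt	1
8bfz	1
7f29	1
5oqv	1
2lnq	2
2lmn	2
2lmo	1
6ti5	1
6ti6	2
2lmp	1
2mpz	1
2m4j	1
5aef	1
8eze	1
6w0o	2
6shs	1
8bfb	1
8ezd	1
2mxu	1
2nao	1
7q4b	1
8azs	1
7q4m	1
8bg0	2
8bg9	2
2mvx	1
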