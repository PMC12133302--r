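entry_id	n_molecules
8cax	1
6tjo	1
7p6d	1
8orf	1
8org	1
6tjx	1
7p6e	1
7p65	1
7u0z	1
7p66	1
7p67	1
7p68	2
7p6a	1
7p6b	1
7p6c	1
8q96	1
8q92	1
6qjh	1
6qjm	1
6qjp	1
6nwp	1
8caq	1
8byn	1
6nwq	1
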