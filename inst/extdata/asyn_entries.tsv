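entry_id	n_molecules
2n0a	1
6a6b	1
6cu7	1
6cu8	1
6h6b	1
6l1t	1
6l1u	3
6l4s	1
6lrq	1
6osj	1
6osl	1
6peo	1
6pes	2
6rt0	1
6rtb	1
6sst	1
6ssx	1
6ufr	1
6xyo	2
6xyp	2
6xyq	2
7c1d	1
7e0f	1
7l7h	2
7nca	2
7ncg	1
7nch	2
7nci	1
7ncj	2
7nck	1
7ozg	1
7ozh	1
7uak	1
7v47	1
7v48	1
7v49	1
7v4a	1
7v4b	1
7v4c	1
7v4d	1
7wmm	1
7wnz	1
7wo0	1
7xjx	1
7xo0	1
7xo1	1
7xo2	1
7xo3	1
7yk2	1
7yk8	1
7yng	1
7ynl	1
7ynm	1
7ynn	1
7yno	1
7ynp	1
7ynq	1
7ynr	1
7yns	1
7ynt	1
8a4l	1
8a9l	1
8ads	1
8adu	1
8adv	1
8adw	1
8aex	2
8cyr	1
8cys	1
8cyt	1
8cyv	2
8cyw	1
8cyx	1
8cyy	2
8cz0	1
8cz1	1
8cz2	1
8cz3	1
8cz6	1
8fpt	1
8h03	1
8h04	1
8h05	1
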