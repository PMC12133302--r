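entry_id	molecule_index	coverage_start	coverage_end	strand_start	strand_end
2beg	1	1	42	18	26
2beg	1	1	42	31	42
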