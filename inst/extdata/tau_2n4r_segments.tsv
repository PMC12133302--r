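protein	start	end	source	threshold
tau_2n4r	276	288	experimental_lb4	60
tau_2n4r	306	321	experimental_lb4	60
tau_2n4r	337	352	experimental_lb4	60
tau_2n4r	373	376	experimental_lb4	60
tau_2n4r	277	286	experimental_lb1	70
tau_2n4r	307	323	experimental_lb1	70
tau_2n4r	338	352	experimental_lb1	70
tau_2n4r	374	376	experimental_lb1	70
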