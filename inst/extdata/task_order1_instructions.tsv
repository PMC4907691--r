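after_trial	onset_s	new_cs_plus
20	320	B
40	650	A
60	980	B
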