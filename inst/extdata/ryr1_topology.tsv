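start	end	compartment
3985	4601	transmembrane
4602	4607	luminal
4608	4937	transmembrane
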