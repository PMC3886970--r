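Speaker	Outcome	Pronunciation	Frequency
english23	with	[wɪθ]	1
english23	her	[hɚɹ]	1
mandarin10	with	[wɪz]	1
serbian10	her	[xɚɹ]	1
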