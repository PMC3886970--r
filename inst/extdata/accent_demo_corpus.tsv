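Speaker	Outcome	Pronunciation	Frequency
english23	with	[wɪθ]	28169384
english167	with	[wɪð]	28169384
english23	her	[hɚɹ]	852131
english167	her	[ɹ̩]	852131
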