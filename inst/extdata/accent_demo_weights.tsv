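Cue	with	her
#wɪ	0.2519	0.0000
wɪθ	0.3738	0.0000
ɪθ#	0.3738	0.0000
wɪð	0.3741	0.0000
ɪð#	0.3741	0.0000
#hɚ	0.0000	0.4973
hɚɹ	0.0000	0.2433
ɚɹ#	0.0000	0.2594
#ɹ#	0.0000	1.0000
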