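Demo fixtures
=============

accent_demo_corpus.tsv   Four-token training excerpt in the style of a
                         transcribed accent archive: two native speakers
                         ('english23', 'english167'), two meanings ('with',
                         'her'), Google-N-gram-scale meaning frequencies
                         already split over the pronunciation variants.
                         IPA symbols are a reconstructed demo rendering,
                         not archive data.
accent_demo_probe.tsv    Probe tokens for activation scoring: the native
                         pronunciations plus two accented ones
                         ('mandarin10' [wɪz], 'serbian10' [xɚɹ]).
accent_demo_weights.tsv  Reference cue-outcome association strengths of a
                         native listener model trained on a 58-speaker
                         archive sample (rounded to 4 decimals); used to
                         demonstrate activation arithmetic with unknown
                         cues contributing zero.
elicitation_paragraph.txt
                         The 69-word elicitation paragraph read by every
                         speaker of the Speech Accent Archive
                         (http://accent.gmu.edu); 55 distinct word types.
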