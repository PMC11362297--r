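# Admissible phoneme clusters for graphemes containing the letter X
# (the single-grapheme-to-cluster exception), one per line,
# phonemes space-separated.
k s
g z
k ʃ
g ʒ
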