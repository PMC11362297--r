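# Attested English syllable onsets, one per line, phonemes space-separated.
# The empty onset is always legal and is not listed.
# Singletons (ŋ and ʒ-initial loanwords excluded; ʒ kept for GENRE-type words)
p
b
t
d
k
g
tʃ
dʒ
f
v
θ
ð
s
z
ʃ
ʒ
h
m
n
l
ɹ
j
w
# Obstruent + liquid / glide
p l
p ɹ
p j
b l
b ɹ
b j
t ɹ
t j
t w
d ɹ
d j
d w
k l
k ɹ
k j
k w
g l
g ɹ
g w
f l
f ɹ
f j
v j
θ ɹ
θ j
θ w
ʃ ɹ
h j
m j
n j
# /s/ + consonant
s p
s t
s k
s f
s m
s n
s l
s w
s j
# /s/ + stop + liquid/glide
s p l
s p ɹ
s p j
s t ɹ
s t j
s k l
s k ɹ
s k w
s k j
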