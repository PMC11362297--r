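# English phoneme inventory (General American, IPA).
# Diphthongs, affricates and rhotic vowels are single tokens.
# columns: symbol, klass (vowel|consonant), manner, sonority (stop < fricative <
# nasal < liquid < glide < vowel)
symbol	klass	manner	sonority
i	vowel	monophthong	6
ɪ	vowel	monophthong	6
ɛ	vowel	monophthong	6
æ	vowel	monophthong	6
ə	vowel	monophthong	6
ʌ	vowel	monophthong	6
u	vowel	monophthong	6
ʊ	vowel	monophthong	6
ɔ	vowel	monophthong	6
ɑ	vowel	monophthong	6
eɪ	vowel	diphthong	6
oʊ	vowel	diphthong	6
aɪ	vowel	diphthong	6
aʊ	vowel	diphthong	6
ɔɪ	vowel	diphthong	6
ɝ	vowel	rhotic	6
ɚ	vowel	rhotic	6
p	consonant	stop	1
b	consonant	stop	1
t	consonant	stop	1
d	consonant	stop	1
k	consonant	stop	1
g	consonant	stop	1
tʃ	consonant	affricate	1
dʒ	consonant	affricate	1
f	consonant	fricative	2
v	consonant	fricative	2
θ	consonant	fricative	2
ð	consonant	fricative	2
s	consonant	fricative	2
z	consonant	fricative	2
ʃ	consonant	fricative	2
ʒ	consonant	fricative	2
h	consonant	fricative	2
m	consonant	nasal	3
n	consonant	nasal	3
ŋ	consonant	nasal	3
l	consonant	liquid	4
ɹ	consonant	liquid	4
j	consonant	glide	5
w	consonant	glide	5
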