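# ARPAbet -> IPA translation for importing CMU-dictionary-style pronunciations.
# Lexical stress digits are stripped on import, except that unstressed AH0/ER0
# map to the reduced vowels (schwa / rhotic schwa).
arpabet	ipa
AA	ɑ
AE	æ
AH0	ə
AH	ʌ
AO	ɔ
AW	aʊ
AY	aɪ
B	b
CH	tʃ
D	d
DH	ð
EH	ɛ
ER0	ɚ
ER	ɝ
EY	eɪ
F	f
G	g
HH	h
IH	ɪ
IY	i
JH	dʒ
K	k
L	l
M	m
N	n
NG	ŋ
OW	oʊ
OY	ɔɪ
P	p
R	ɹ
S	s
SH	ʃ
T	t
TH	θ
UH	ʊ
UW	u
V	v
W	w
Y	j
Z	z
ZH	ʒ
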