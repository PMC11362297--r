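# sublexr demonstration lexicon: a small hand-curated set of common English
# words with phoneme-grapheme alignments in the package's mapping notation.
# It exists to exercise and illustrate the machinery; it is NOT a published
# norm corpus, and measures computed from it are demonstration values only.
spelling	pronunciation	mapping	pron_id
CAT	kæt	C>k|A>æ|T>t	1
COT	kɑt	C>k|O>ɑ|T>t	1
CUT	kʌt	C>k|U>ʌ|T>t	1
DOG	dɔg	D>d|O>ɔ|G>g	1
BIG	bɪg	B>b|I>ɪ|G>g	1
BAT	bæt	B>b|A>æ|T>t	1
MAP	mæp	M>m|A>æ|P>p	1
PEN	pɛn	P>p|E>ɛ|N>n	1
PET	pɛt	P>p|E>ɛ|T>t	1
SIT	sɪt	S>s|I>ɪ|T>t	1
RUN	ɹʌn	R>ɹ|U>ʌ|N>n	1
LEG	lɛg	L>l|E>ɛ|G>g	1
GAS	gæs	G>g|A>æ|S>s	1
BUS	bʌs	B>b|U>ʌ|S>s	1
YES	jɛs	Y>j|E>ɛ|S>s	1
THIS	ðɪs	TH>ð|I>ɪ|S>s	1
PLUS	plʌs	P>p|L>l|U>ʌ|S>s	1
HIS	hɪz	H>h|I>ɪ|S>z	1
HAS	hæz	H>h|A>æ|S>z	1
IS	ɪz	I>ɪ|S>z	1
WAS	wʌz	W>w|A>ʌ|S>z	1
STOP	stɑp	S>s|T>t|O>ɑ|P>p	1
STEP	stɛp	S>s|T>t|E>ɛ|P>p	1
SPIN	spɪn	S>s|P>p|I>ɪ|N>n	1
SKIN	skɪn	S>s|K>k|I>ɪ|N>n	1
TRIP	tɹɪp	T>t|R>ɹ|I>ɪ|P>p	1
GRIN	gɹɪn	G>g|R>ɹ|I>ɪ|N>n	1
KIN	kɪn	K>k|I>ɪ|N>n	1
WIN	wɪn	W>w|I>ɪ|N>n	1
CHIN	tʃɪn	CH>tʃ|I>ɪ|N>n	1
SHIP	ʃɪp	SH>ʃ|I>ɪ|P>p	1
FISH	fɪʃ	F>f|I>ɪ|SH>ʃ	1
WISH	wɪʃ	W>w|I>ɪ|SH>ʃ	1
PLEASE	pliz	P>p|L>l|EA_E>i|S>z	1
TEASE	tiz	T>t|EA_E>i|S>z	1
EASE	iz	EA_E>i|S>z	1
LEASE	lis	L>l|EA_E>i|S>s	1
CEASE	sis	C>s|EA_E>i|S>s	1
GREASE	gɹis	G>g|R>ɹ|EA_E>i|S>s	1
CREASE	kɹis	C>k|R>ɹ|EA_E>i|S>s	1
BAKE	beɪk	B>b|A_E>eɪ|K>k	1
TAKE	teɪk	T>t|A_E>eɪ|K>k	1
MAKE	meɪk	M>m|A_E>eɪ|K>k	1
LAKE	leɪk	L>l|A_E>eɪ|K>k	1
NAME	neɪm	N>n|A_E>eɪ|M>m	1
GAME	geɪm	G>g|A_E>eɪ|M>m	1
CANE	keɪn	C>k|A_E>eɪ|N>n	1
PLANE	pleɪn	P>p|L>l|A_E>eɪ|N>n	1
POSE	poʊz	P>p|O_E>oʊ|S>z	1
NOSE	noʊz	N>n|O_E>oʊ|S>z	1
ROSE	ɹoʊz	R>ɹ|O_E>oʊ|S>z	1
CLOSE	kloʊs	C>k|L>l|O_E>oʊ|S>s	1
GONE	gɔn	G>g|O_E>ɔ|N>n	1
ROGUE	ɹoʊg	R>ɹ|O_E>oʊ|GU>g	1
GUESS	gɛs	GU>g|E>ɛ|SS>s	1
LEAGUE	lig	L>l|EA_E>i|GU>g	1
WEIGH	weɪ	W>w|EIGH>eɪ	1
WEIGHT	weɪt	W>w|EIGH>eɪ|T>t	1
EIGHT	eɪt	EIGH>eɪ|T>t	1
ONE	wʌn	O>w|E~ʌ|N>n	1
BEAD	bid	B>b|EA>i|D>d	1
BEAN	bin	B>b|EA>i|N>n	1
TEAM	tim	T>t|EA>i|M>m	1
LEAD	lɛd	L>l|EA>ɛ|D>d	1
LEAD	lid	L>l|EA>i|D>d	2
HEAD	hɛd	H>h|EA>ɛ|D>d	1
BREAD	bɹɛd	B>b|R>ɹ|EA>ɛ|D>d	1
SEE	si	S>s|EE>i	1
SEEN	sin	S>s|EE>i|N>n	1
GREEN	gɹin	G>g|R>ɹ|EE>i|N>n	1
TREE	tɹi	T>t|R>ɹ|EE>i	1
BLEED	blid	B>b|L>l|EE>i|D>d	1
BLACK	blæk	B>b|L>l|A>æ|CK>k	1
CLOCK	klɑk	C>k|L>l|O>ɑ|CK>k	1
TRICK	tɹɪk	T>t|R>ɹ|I>ɪ|CK>k	1
FOX	fɑks	F>f|O>ɑ|X>ks	1
BOX	bɑks	B>b|O>ɑ|X>ks	1
SIX	sɪks	S>s|I>ɪ|X>ks	1
MIX	mɪks	M>m|I>ɪ|X>ks	1
TAX	tæks	T>t|A>æ|X>ks	1
MOON	mun	M>m|OO>u|N>n	1
SOON	sun	S>s|OO>u|N>n	1
FOOD	fud	F>f|OO>u|D>d	1
PHONE	foʊn	PH>f|O_E>oʊ|N>n	1
GRAPH	gɹæf	G>g|R>ɹ|A>æ|PH>f	1
STUFF	stʌf	S>s|T>t|U>ʌ|FF>f	1
OFF	ɔf	O>ɔ|FF>f	1
CHEESE	tʃiz	CH>tʃ|EE_E>i|S>z	1
STRING	stɹɪŋ	S>s|T>t|R>ɹ|I>ɪ|NG>ŋ	1
SPRING	spɹɪŋ	S>s|P>p|R>ɹ|I>ɪ|NG>ŋ	1
RHYME	ɹaɪm	RH>ɹ|Y_E>aɪ|M>m	1
TIME	taɪm	T>t|I_E>aɪ|M>m	1
LIME	laɪm	L>l|I_E>aɪ|M>m	1
RIDE	ɹaɪd	R>ɹ|I_E>aɪ|D>d	1
BID	bɪd	B>b|I>ɪ|D>d	1
SKI	ski	S>s|K>k|I>i	1
HAPPY	hæpi	H>h|A>æ-PP>p|Y>i	1
LOBSTER	lɑbstəɹ	L>l|O>ɑ|B>b-S>s|T>t|E>ə|R>ɹ	1
EATER	itəɹ	EA>i-T>t|E>ə|R>ɹ	1
TAXI	tæksi	T>t|A>æ|X>ks-I>i	1
EXIT	ɛksɪt	E>ɛ|X>ks-I>ɪ|T>t	1
BASIN	beɪsɪn	B>b|A>eɪ-S>s|I>ɪ|N>n	1
PAPER	peɪpəɹ	P>p|A>eɪ-P>p|E>ə|R>ɹ	1
OPEN	oʊpən	O>oʊ-P>p|E>ə|N>n	1
MUSCLE	mʌskəl	M>m|U>ʌ-S>s|C>k|E~ə|L>l	1
MUSSEL	mʌsəl	M>m|U>ʌ-SS>s|E>ə|L>l	1
TABLE	teɪbəl	T>t|A>eɪ-B>b|E~ə|L>l	1
MAPLE	meɪpəl	M>m|A>eɪ-P>p|E~ə|L>l	1
LITTLE	lɪtəl	L>l|I>ɪ-TT>t|E~ə|L>l	1
APPLE	æpəl	A>æ-PP>p|E~ə|L>l	1
THEATRE	θiətəɹ	TH>θ|E>i-A>ə-T>t|E~ə|R>ɹ	1
CAFE	kəfeɪ	C>k|A>ə-F>f|E>eɪ	1
LATTE	lɑteɪ	L>l|A>ɑ-TT>t|E>eɪ	1
MAYBE	meɪbi	M>m|AY>eɪ-B>b|E>i	1
BABY	beɪbi	B>b|A>eɪ-B>b|Y>i	1
PONY	poʊni	P>p|O>oʊ-N>n|Y>i	1
SODA	soʊdə	S>s|O>oʊ-D>d|A>ə	1
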