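wt	codon	mut	tkis
M	237	V	imatinib
I	242	T	imatinib
M	244	V	imatinib
K	247	R	imatinib
L	248	V	imatinib
G	250	E	imatinib
G	250	R	imatinib
Q	252	H	imatinib
Q	252	R	imatinib
Y	253	F	imatinib
Y	253	H	imatinib;nilotinib
E	255	K	imatinib;nilotinib;bosutinib
E	255	V	imatinib;nilotinib;bosutinib
E	258	D	imatinib
W	261	L	imatinib
L	273	M	imatinib
E	275	K	imatinib
E	275	Q	imatinib
D	276	G	imatinib
T	277	A	imatinib
E	279	K	imatinib
V	280	A	imatinib
V	289	A	imatinib
V	289	I	imatinib
E	292	Q	imatinib
E	292	V	imatinib
I	293	V	imatinib
L	298	V	imatinib
V	299	L	dasatinib;bosutinib
F	311	I	imatinib
F	311	L	imatinib
T	315	A	dasatinib
T	315	I	imatinib;dasatinib;nilotinib;bosutinib
T	315	L	ponatinib
T	315	M	ponatinib
F	317	C	imatinib;dasatinib
F	317	I	imatinib;dasatinib
F	317	L	imatinib;dasatinib
F	317	V	imatinib;dasatinib
Y	320	C	imatinib
L	324	Q	imatinib
Y	342	H	imatinib
M	343	T	imatinib
A	344	V	imatinib
A	350	V	imatinib
M	351	T	imatinib
E	355	A	imatinib
E	355	D	imatinib
E	355	G	imatinib
F	359	C	imatinib;nilotinib
F	359	I	imatinib;nilotinib
F	359	L	imatinib
F	359	V	imatinib;nilotinib
D	363	Y	imatinib
L	364	I	imatinib
A	365	V	imatinib
A	366	G	imatinib
L	370	P	imatinib
V	371	A	imatinib
E	373	K	imatinib
V	379	I	imatinib
A	380	T	imatinib
F	382	L	imatinib
L	384	M	imatinib
L	387	F	imatinib
L	387	V	imatinib
M	388	L	imatinib
H	396	A	imatinib
H	396	P	imatinib
H	396	R	imatinib
A	397	P	imatinib
S	417	F	imatinib
S	417	Y	imatinib
I	418	S	imatinib
I	418	V	imatinib
A	433	T	imatinib
S	438	C	imatinib
E	450	A	imatinib
E	450	G	imatinib
E	450	K	imatinib
E	450	V	imatinib
E	453	A	imatinib
E	453	G	imatinib
E	453	K	imatinib
E	453	Q	imatinib
E	453	V	imatinib
E	459	G	imatinib
E	459	K	imatinib
E	459	Q	imatinib
E	459	V	imatinib
M	472	I	imatinib
P	480	L	imatinib
F	486	S	imatinib
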