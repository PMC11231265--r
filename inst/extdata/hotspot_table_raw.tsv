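tki	tokens
imatinib	M237V,I242T,M244 V,K247R,L248V,G250E,G250R,Q252R,Q252H,Y253F,Y253H,E255K,E255V,E258D,W261L,L273M,E275K,E275Q,D276G,T277A,E279K,V280A,V289I,V289I,V289A,E292Q,E292V,I293V,L298V,F311L,F311I,T315I,F317L,F317V,F317I,F317C,Y320C,L324Q,Y342H,M343T,A344V,A350V,M351T,E355D,E355G,E355A,F359V,F359I,F359C,F359L,D363Y,L364I,A365V,A366G,L370P,V371A,E373K,V379I,A380T,F382L,L384M,L387F,L387V,M388L,H396R,H396P,H396A,A397P,S417F,S417Y,I418S,I418V,A433T,S438C,E450K,E450G,E450A,E450V,E453G,E453A,E453K,E453V,E453Q,E459K,E459V,E459G,E459Q,M472I,P480L,F486S
dasatinib	V299L,T315I,T315A,F317L,F317V,F317I,F317C
nilotinib	Y253H,E255K,E255V,T315I,F359V,F359I,F359C
bosutinib	E255V,E255K,V299L,T315I
ponatinib	T315M,T315L
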