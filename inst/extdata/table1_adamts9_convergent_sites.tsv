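# ADAMTS9 convergent-site character matrix: 15 taxa x 21 alignment columns.
# Column headers are 1-based amino-acid positions in the original alignment.
taxon	54	236	244	324	362	512	558	565	775	838	884	890	1110	1314	1319	1489	1497	1597	1675	1765	1933
Naked_mole_rat	V	R	R	V	P	S	D	Q	A	K	V	R	Q	R	R	R	E	R	A	S	T
Eptesicus_fuscus	V	R	R	V	P	S	D	Q	A	K	V	R	Q	R	R	R	E	R	A	S	T
Myotis_brandtii	V	R	R	V	P	S	D	Q	A	K	V	R	Q	R	R	-	-	R	A	S	T
Myotis_lucifugus	V	V	Q	V	P	S	D	Q	A	K	V	R	Q	R	R	R	E	R	A	S	T
Rat	I	K	K	I	S	P	-	-	T	S	I	R	E	Q	T	K	D	Q	T	N	L
Mouse	I	K	K	I	Y	P	H	R	T	S	I	K	E	Q	T	K	D	Q	T	N	K
Prairie_vole	I	K	K	I	S	P	H	R	T	S	I	K	E	Q	T	K	D	Q	T	N	K
Hamster	I	K	K	I	S	P	H	R	T	N	I	K	E	Q	R	K	D	Q	T	N	K
Star_nosed_mole	I	K	K	I	S	S	P	R	T	N	V	K	E	Q	S	K	D	K	T	K	K
Shrew	-	K	K	I	S	X	L	R	T	N	V	K	E	Q	S	X	X	K	T	L	K
Ferret	I	K	K	I	S	P	-	R	T	N	I	K	E	Q	S	K	D	K	T	E	K
Tree_shrew	V	K	K	I	X	P	X	X	T	X	-	K	E	Q	S	K	E	K	X	X	K
Hedgehog	-	S	K	I	S	Y	H	R	X	N	V	K	E	Q	D	K	D	K	T	N	K
Opossum	-	K	R	V	A	P	H	R	T	N	I	S	A	R	R	K	D	K	T	K	K
Pika	I	S	K	V	S	P	H	R	T	N	I	K	E	Q	M	K	D	K	A	Q	K
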