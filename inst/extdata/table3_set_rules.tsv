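set	ovine_set	cdr1_lengths	residue_57	w107	exceptions
1	1C	7	G	-	
2	1B	7	Y	+/-	TRDV1t cdr1=8
3	1D/1C	9	E	+/-	
4	1A	9	Y	-	
5	1A	9	Y	+	TRDV1d Q-at-107
6	1A	9	Y,N	-	
7	NA	5,10	A,V	+	
8	1A	9	Y	+	
9	1E	7	lacks	+/-	TRDV1o cdr1=18
10	1E	7	N,G	+	
11	1E	7	G,V	+	
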