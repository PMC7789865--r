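amino_acid	codon	n_high	n_low	source
Phe	UUU	1118	265	printed
Phe	UUC	567	986	printed
Leu	UUA	631	110	printed
Leu	UUG	861	388	printed
Leu	CUU	884	294	printed
Leu	CUC	257	1132	printed
Leu	CUA	325	162	printed
Leu	CUG	365	564	printed
Ile	AUU	1010	301	printed
Ile	AUC	444	790	printed
Ile	AUA	542	199	printed
Met	AUG	967	676	printed
Val	GUU	1045	337	printed
Val	GUC	304	735	printed
Val	GUA	463	146	printed
Val	GUG	579	858	printed
Ser	UCU	1103	338	printed
Ser	UCC	349	873	printed
Ser	UCA	976	225	printed
Ser	UCG	146	500	printed
Ser	AGU	669	166	printed
Ser	AGC	373	548	printed
Pro	CCU	829	339	printed
Pro	CCC	167	619	printed
Pro	CCA	666	228	printed
Pro	CCG	62	660	printed
Thr	ACU	846	247	printed
Thr	ACC	252	731	printed
Thr	ACA	752	195	printed
Thr	ACG	90	432	printed
Ala	GCU	1023	491	printed
Ala	GCC	250	1260	printed
Ala	GCA	1005	318	printed
Ala	GCG	83	738	printed
Tyr	UAU	779	126	printed
Tyr	UAC	365	689	printed
His	CAU	750	169	printed
His	CAC	249	540	printed
Gln	CAA	846	287	printed
Gln	CAG	626	619	printed
Asn	AAU	1231	260	printed
Asn	AAC	562	787	printed
Lys	AAA	1149	290	printed
Lys	AAG	1193	956	printed
Asp	GAU	1708	489	printed
Asp	GAC	539	908	inferred
Cys	UGU	621	146	printed
Cys	UGC	229	449	printed
Trp	UGG	412	383	printed
Arg	CGU	244	115	printed
Arg	CGC	71	407	printed
Arg	CGA	124	167	printed
Arg	CGG	67	347	printed
Arg	AGA	852	191	printed
Arg	AGG	529	452	printed
Gly	GGU	724	338	printed
Gly	GGC	501	737	inferred
Gly	GGA	501	738	inferred
Gly	GGG	502	738	inferred
Ter	UAA	49	48	printed
Ter	UAG	30	30	printed
Ter	UGA	53	54	printed
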