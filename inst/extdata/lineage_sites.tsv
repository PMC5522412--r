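# Lineage-specific candidate selected sites with the posterior probability
# that the population-scaled selection coefficient is >= 1.
gene_id	lineage	codon_index	ancestral_aa	derived_aa	pr_gamma_ge_1
GORASP2	human	257	Ala	Thr	0.901
GORASP2	gorilla	247	Pro	Ser	0.988
HSPA4	human	778	Ile	Thr	0.982
MDM2	human	283	Arg	Gln	0.960
MDM2	human	432	Met	Val	0.961
MDM2	gorilla	413	Ser	Cys	0.948
MYC	human	369	Asp	Val	0.874
MYC	chimpanzee	224	Ala	Pro	0.872
PSMA7	human	216	Pro	Ser	0.911
RAB2A	gorilla	197	Thr	Ser	0.752
RB1	human	233	Val	Met	0.947
SETD5	chimpanzee	421	Thr	Ala	0.759
SETD5	chimpanzee	563	Pro	Ala	0.760
SMARCC1	human	117	Thr	Ala	0.850
SMARCC1	human	437	Pro	Leu	0.851
SYT1	gorilla	420	Val	Ile	0.902
TRAF2	human	237	Ala	Val	0.963
TRAF2	human	258	Ser	Leu	0.963
TRAF2	human	373	Thr	Ile	0.935
TRAF2	gorilla	221	Ile	Val	0.781
UIMC1	chimpanzee	429	Arg	Gly	0.958
UIMC1	chimpanzee	439	Ala	Thr	0.960
UIMC1	chimpanzee	511	Arg	His	0.911
UIMC1	chimpanzee	597	Ser	Gly	0.974
UIMC1	chimpanzee	601	Cys	Phe	0.974
UIMC1	gorilla	16	Asn	Ile	0.913
UIMC1	gorilla	62	Thr	Ala	0.894
UIMC1	gorilla	502	Gln	His	0.764
UIMC1	gorilla	581	Ser	Cys	0.775
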