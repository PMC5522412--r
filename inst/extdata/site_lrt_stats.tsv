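# Site-model LRT statistics (2*delta lnL, F3X4 codon frequencies) and the
# published adjusted p values for module genes significant in the extended
# mammalian phylogeny. M7 is the neutral beta model, M8 adds a positive
# selection class, M8a constrains that class to neutrality.
gene_id	module	test_id	stat	df	p_printed
MDM2	M1	M7_vs_M8	33.357	2	1.142e-7
MDM2	M1	M8a_vs_M8	4.683	1	3.047e-2
MECP2	M1	M7_vs_M8	11.692	2	5.782e-3
MECP2	M1	M8a_vs_M8	7.593	1	5.860e-3
MYC	M1	M7_vs_M8	18.374	2	1.023e-4
MYC	M1	M8a_vs_M8	16.927	1	7.768e-5
SMARCC2	M1	M7_vs_M8	55.960	2	1.411e-12
SMARCC2	M1	M8a_vs_M8	18.189	1	2.000e-5
UIMC1	M1	M7_vs_M8	147.783	2	1.623e-32
UIMC1	M1	M8a_vs_M8	87.994	1	6.566e-21
GRIN2A	M2	M7_vs_M8	82.719	2	2.181e-18
GRIN2A	M2	M8a_vs_M8	58.105	1	2.485e-14
MAP1A	M2	M7_vs_M8	189.749	2	1.252e-41
MAP1A	M2	M8a_vs_M8	147.643	1	5.678e-34
SYNGAP1	M2	M7_vs_M8	33.228	2	1.218e-7
SYNGAP1	M2	M8a_vs_M8	17.161	1	3.433e-5
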