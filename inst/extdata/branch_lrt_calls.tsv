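# Branch-site LRT outcomes (FDR-adjusted p) for the genes of the M1/M2
# neurodevelopmental-disorder modules with at least one significant branch.
# The F61 arm of each test is reported as confirmed/unconfirmed in the
# source table; confirmed arms are recoded here with the F3X4 p value and
# unconfirmed arms with p = 0.5, preserving the threshold semantics of the
# dual codon-frequency declaration rule. Remaining module genes (39 in M1,
# 15 in M2) had no significant branch and are omitted.
gene_id	module	branch	codon_freq	stat	p_adj
CHD8	M1	mammalia	F3X4	58.044	2.56e-14
CHD8	M1	mammalia	F61	NA	2.56e-14
CHD8	M1	sauropsida	F3X4	76.290	4.90e-18
CHD8	M1	sauropsida	F61	NA	4.90e-18
HSPA4	M1	mammalia	F3X4	0	1
HSPA4	M1	mammalia	F61	NA	1
HSPA4	M1	sauropsida	F3X4	11.083	1.74e-3
HSPA4	M1	sauropsida	F61	NA	1.74e-3
MDM2	M1	mammalia	F3X4	12.255	9.28e-4
MDM2	M1	mammalia	F61	NA	9.28e-4
MDM2	M1	sauropsida	F3X4	0	1
MDM2	M1	sauropsida	F61	NA	1
MECP2	M1	mammalia	F3X4	4.950	2.61e-2
MECP2	M1	mammalia	F61	NA	2.61e-2
MECP2	M1	sauropsida	F3X4	21.963	5.56e-6
MECP2	M1	sauropsida	F61	NA	5.56e-6
MYC	M1	mammalia	F3X4	10.527	2.35e-3
MYC	M1	mammalia	F61	NA	2.35e-3
MYC	M1	sauropsida	F3X4	8.519	3.51e-3
MYC	M1	sauropsida	F61	NA	0.5
RB1	M1	mammalia	F3X4	0	1
RB1	M1	mammalia	F61	NA	1
RB1	M1	sauropsida	F3X4	15.493	1.66e-4
RB1	M1	sauropsida	F61	NA	1.66e-4
SMARCC2	M1	mammalia	F3X4	15.721	1.47e-4
SMARCC2	M1	mammalia	F61	NA	1.47e-4
SMARCC2	M1	sauropsida	F3X4	0	1
SMARCC2	M1	sauropsida	F61	NA	1
UIMC1	M1	mammalia	F3X4	7.634	7.85e-3
UIMC1	M1	mammalia	F61	NA	7.85e-3
UIMC1	M1	sauropsida	F3X4	7.068	7.85e-3
UIMC1	M1	sauropsida	F61	NA	7.85e-3
DLG4	M2	mammalia	F3X4	5.320	4.22e-2
DLG4	M2	mammalia	F61	NA	4.22e-2
DLG4	M2	sauropsida	F3X4	0	1
DLG4	M2	sauropsida	F61	NA	1
GRIN2A	M2	mammalia	F3X4	5.974	1.73e-2
GRIN2A	M2	mammalia	F61	NA	1.73e-2
GRIN2A	M2	sauropsida	F3X4	5.667	1.73e-2
GRIN2A	M2	sauropsida	F61	NA	0.5
GRIN2B	M2	mammalia	F3X4	0	1
GRIN2B	M2	mammalia	F61	NA	1
GRIN2B	M2	sauropsida	F3X4	8.337	7.77e-3
GRIN2B	M2	sauropsida	F61	NA	7.77e-3
KCNMA1	M2	mammalia	F3X4	18.850	1.44e-5
KCNMA1	M2	mammalia	F61	NA	1.44e-5
KCNMA1	M2	sauropsida	F3X4	18.811	1.44e-5
KCNMA1	M2	sauropsida	F61	NA	1.44e-5
MAP1A	M2	mammalia	F3X4	61.374	9.44e-15
MAP1A	M2	mammalia	F61	NA	9.44e-15
MAP1A	M2	sauropsida	F3X4	32.349	1.29e-8
MAP1A	M2	sauropsida	F61	NA	1.29e-8
SYNGAP1	M2	mammalia	F3X4	64.996	1.50e-15
SYNGAP1	M2	mammalia	F61	NA	1.50e-15
SYNGAP1	M2	sauropsida	F3X4	26.360	2.83e-7
SYNGAP1	M2	sauropsida	F61	NA	2.83e-7
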