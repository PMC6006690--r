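name	biocyc_id	producible_pre_gapfill
(2E,6E)-farnesyl diphosphate	FARNESYL-PP	false
1-deoxy-D-xylulose 5-phosphate	DEOXYXYLULOSE-5P	false
2-C-methyl-D-erythritol 4-phosphate	2-C-METHYL-D-ERYTHRITOL-4-PHOSPHATE	false
2-C-methyl-D-erythritol-2,4-cyclodiphosphate	2C-METH-D-ERYTHRITOL-CYCLODIPHOSPHATE	false
2-phospho-4-(cytidine 5'-diphospho)-2-C-methyl-D-erythritol	2-PHOSPHO-4-CYTIDINE-5-DIPHOSPHO-2-C-MET	false
ADP	ADP	true
ADP-alpha-D-glucose	ADP-D-GLUCOSE	true
AMP	AMP	true
ATP	ATP	true
CDP-1,2-dipalmitoylglycerol	CPD-12815	false
CTP	CTP	false
GMP	GMP	true
GTP	GTP	true
H+	PROTON	true
H2O	WATER	true
L-alanine	L-ALPHA-ALANINE	false
L-arginine	ARG	false
L-asparagine	ASN	false
L-aspartate	L-ASPARTATE	false
L-cysteine	CYS	false
L-glutamate	GLT	false
L-glutamine	GLN	false
L-histidine	HIS	false
L-isoleucine	ILE	false
L-leucine	LEU	false
L-lysine	LYS	false
L-methionine	MET	false
L-phenylalanine	PHE	false
L-proline	PRO	false
L-serine	SER	false
L-threonine	THR	false
L-tryptophan	TRP	false
L-tyrosine	TYR	false
L-valine	VAL	false
NAD+	NAD	true
NADH	NADH	true
NADP+	NADP	true
NADPH	NADPH	true
S-adenosyl-L-methionine	S-ADENOSYLMETHIONINE	true
UDP-N-acetyl-alpha-D-glucosamine	UDP-N-ACETYL-D-GLUCOSAMINE	false
C1	C1	false
UTP	UTP	false
chorismate	CHORISMATE	true
dATP	DATP	false
dCTP	DCTP	false
dGTP	DGTP	false
dTTP	TTP	false
di-trans,octa-cis-undecaprenyl diphosphate	UNDECAPRENYL-DIPHOSPHATE	false
dipalmitoyl phosphatidate	CPD0-1422	false
C6	C6	false
glycine	GLY	false
isopentenyl diphosphate	DELTA3-ISOPENTENYL-PP	false
phosphate	Pi	true
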