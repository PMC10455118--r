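family	activity_code	substrate	provenance
# Curated CAZy (sub-)family -> enzyme activity -> plant polysaccharide catalog.
# Cellulose
GH5_4	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH5_5	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH5_22	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH12	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH45	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH131	EGL	cellulose	cellulose degradation: endoglucanases in GH12, GH131, GH45 and GH5 subfamilies GH5_4, GH5_5, GH5_22
GH7	CBH	cellulose	cellulose degradation: cellobiohydrolase I in GH7
GH6	CBH	cellulose	cellulose degradation: cellobiohydrolase II in GH6
GH1	BGL	cellulose	cellulose degradation: beta-glucosidases in GH1 and GH3
GH3	BGL	cellulose	cellulose degradation: beta-glucosidases in GH1 and GH3
AA9	LPMO	cellulose	cellulose degradation: lytic polysaccharide monooxygenases AA9 and AA16
AA16	LPMO	cellulose	cellulose degradation: lytic polysaccharide monooxygenases AA9 and AA16
AA3_1	CDH	cellulose	cellulose degradation: cellobiose dehydrogenase in AA3_1
# Xylan
GH10	XLN	xylan	xylan degradation: beta-D-endoxylanase from GH10 and GH11
GH11	XLN	xylan	xylan degradation: beta-D-endoxylanase from GH10 and GH11
GH30_7	XBH	xylan	xylan degradation: beta-xylobiohydrolase from GH30_7
GH3	BXL	xylan	xylan degradation: beta-xylosidase from GH3 and GH43
GH43	BXL	xylan	xylan degradation: beta-xylosidase from GH3 and GH43
GH43	ABF	xylan	xylan degradation: alpha-L-arabinofuranosidase from GH43, GH51, GH54
GH51	ABF	xylan	xylan degradation: alpha-L-arabinofuranosidase from GH43, GH51, GH54
GH54	ABF	xylan	xylan degradation: alpha-L-arabinofuranosidase from GH43, GH51, GH54
GH62	AXH	xylan	xylan degradation: arabinoxylan arabinofuranohydrolase from GH62
GH67	AGU	xylan	xylan degradation: alpha-glucuronidase from GH67 and GH115
GH115	AGU	xylan	xylan degradation: alpha-glucuronidase from GH67 and GH115
CE15	GE	xylan	xylan degradation: glucuronoyl esterase in CE15
CE1	AXE	xylan	xylan degradation: acetyl xylan esterase from CE1 and CE5
CE5	AXE	xylan	xylan degradation: acetyl xylan esterase from CE1 and CE5
CE16	HAE	xylan	xylan degradation: hemicellulose acetyl esterase from CE16
FAE	FAE	xylan	xylan degradation: feruloyl esterase on arabinoxylan ferulic acid decorations
# Xyloglucan
GH29	AFC	xyloglucan	xyloglucan degradation: alpha-fucosidase from GH29, GH95, GH141
GH95	AFC	xyloglucan	xyloglucan degradation: alpha-fucosidase from GH29, GH95, GH141
GH141	AFC	xyloglucan	xyloglucan degradation: alpha-fucosidase from GH29, GH95, GH141
GH12	XEG	xyloglucan	xyloglucan degradation: xyloglucan beta-1,4-endoglucanase from GH12, GH44, GH74
GH44	XEG	xyloglucan	xyloglucan degradation: xyloglucan beta-1,4-endoglucanase from GH12, GH44, GH74
GH74	XEG	xyloglucan	xyloglucan degradation: xyloglucan beta-1,4-endoglucanase from GH12, GH44, GH74
GH31	AXL	xyloglucan	xyloglucan degradation: alpha-xylosidase from GH31
GH2	LAC	xyloglucan	xyloglucan degradation: beta-1,4-galactosidase from GH2 and GH35
GH35	LAC	xyloglucan	xyloglucan degradation: beta-1,4-galactosidase from GH2 and GH35
GH43	ABF	xyloglucan	xyloglucan degradation: arabinofuranosidases act on xyloglucan side chains
GH51	ABF	xyloglucan	xyloglucan degradation: arabinofuranosidases act on xyloglucan side chains
GH54	ABF	xyloglucan	xyloglucan degradation: arabinofuranosidases act on xyloglucan side chains
CE16	HAE	xyloglucan	xyloglucan degradation: hemicellulose acetyl esterase acts on xyloglucan
# Mannan
GH5_7	MAN	mannan	mannan degradation: beta-1,4-endomannanase mainly in GH5_7, fewer in GH26 and GH134
GH26	MAN	mannan	mannan degradation: beta-1,4-endomannanase mainly in GH5_7, fewer in GH26 and GH134
GH134	MAN	mannan	mannan degradation: beta-1,4-endomannanase mainly in GH5_7, fewer in GH26 and GH134
GH2	MND	mannan	mannan degradation: beta-1,4-mannosidase in GH2
GH27	AGL	mannan	mannan degradation: alpha-galactosidases in GH27 and GH36
GH36	AGL	mannan	mannan degradation: alpha-galactosidases in GH27 and GH36
CE16	HAE	mannan	mannan degradation: hemicellulose acetyl esterase in CE16
# Pectin
GH2	LAC	pectin	pectin degradation: hydrolases incl. GH2, GH5_16, GH28, GH35, GH43, GH51, GH54, GH78, GH88, GH93, GH105
GH35	LAC	pectin	pectin degradation: hydrolases incl. GH2, GH5_16, GH28, GH35, GH43, GH51, GH54, GH78, GH88, GH93, GH105
GH5_16	GAL	pectin	pectin degradation: hydrolases incl. GH5_16
GH53	GAL	pectin	pectin degradation: endo-beta-1,4-galactanase GH53 (absent in T. reesei among pectinolytic GH families)
GH28	PGA	pectin	pectin degradation: polygalacturonan hydrolases in GH28
GH43	ABF	pectin	pectin degradation: arabinan side-chain arabinofuranosidases GH43, GH51, GH54
GH51	ABF	pectin	pectin degradation: arabinan side-chain arabinofuranosidases GH43, GH51, GH54
GH54	ABF	pectin	pectin degradation: arabinan side-chain arabinofuranosidases GH43, GH51, GH54
GH78	RHA	pectin	pectin degradation: alpha-rhamnosidase in GH78
GH88	UGH	pectin	pectin degradation: unsaturated glucuronyl hydrolase in GH88
GH93	ABN	pectin	pectin degradation: exo-arabinanase in GH93
GH105	URH	pectin	pectin degradation: unsaturated rhamnogalacturonyl hydrolase in GH105
PL1	PLY	pectin	pectin degradation: pectin/pectate lyases PL1, PL3, PL4, PL9, PL11
PL3	PLY	pectin	pectin degradation: pectin/pectate lyases PL1, PL3, PL4, PL9, PL11
PL4	PLY	pectin	pectin degradation: pectin/pectate lyases PL1, PL3, PL4, PL9, PL11
PL9	PLY	pectin	pectin degradation: pectin/pectate lyases PL1, PL3, PL4, PL9, PL11
PL11	PLY	pectin	pectin degradation: pectin/pectate lyases PL1, PL3, PL4, PL9, PL11
CE8	PME	pectin	pectin degradation: pectin methylesterase in CE8
CE12	RGAE	pectin	pectin degradation: pectin/rhamnogalacturonan acetyl esterase in CE12
FAE	FAE	pectin	pectin degradation: feruloyl esterase on ferulic acid esters of pectin side chains
# Starch
GH13_40	AGD	starch	starch degradation: alpha-glucosidase from GH13_40 and GH31
GH31	AGD	starch	starch degradation: alpha-glucosidase from GH13_40 and GH31
GH133	AMG	starch	starch degradation: amylo-alpha-1,6-glucosidase from GH133
GH13_1	AMY	starch	starch degradation: alpha-amylase from GH13_1 and GH13_5
GH13_5	AMY	starch	starch degradation: alpha-amylase from GH13_1 and GH13_5
GH15	GLA	starch	starch degradation: glucoamylase from GH15
AA13	LPMO	starch	starch degradation: starch-active lytic polysaccharide monooxygenase AA13
# Inulin
GH32	INU	inulin	inulin degradation: GH32 is the only CAZy family (endo-inulinase, exo-inulinase, invertase)
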