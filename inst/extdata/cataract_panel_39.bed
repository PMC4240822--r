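chr1	16450000	16482000	EPHA2
chr1	47881000	47885000	FOXE3
chr1	147379240	147402128	GJA8
chr2	208986000	208990000	CRYGD
chr2	208992000	208997000	CRYGC
chr2	209007000	209013000	CRYGB
chr2	209022000	209030000	CRYGA
chr2	219854000	219858000	CRYBA2
chr3	45959000	46037000	FYCO1
chr3	133119000	133194000	BFSP2
chr3	184063000	184069000	CRYGS
chr4	6271000	6305000	WFS1
chr6	10492000	10629000	GCNT2
chr7	141251000	141354000	AGK
chr8	72109000	72274000	EYA1
chr9	100174000	100242000	TDRD7
chr10	17270000	17280000	VIM
chr10	91190000	91294000	SLC16A12
chr10	103989000	104001000	PITX3
chr11	31806000	31839000	PAX6
chr11	111779000	111784000	CRYAB
chr12	56844000	56849000	MIP
chr13	20716000	20735000	GJA3
chr16	67197000	67204000	HSF4
chr16	79627000	79635000	MAF
chr17	27573000	27582000	CRYBA1
chr17	33478000	33530000	UNC45B
chr17	73754000	73761000	GALK1
chr19	38397000	38644000	SIPA1L3
chr19	49468000	49471000	FTL
chr19	51882000	51890000	LIM2
chr20	17474000	17548000	BFSP1
chr20	32399000	32442000	CHMP4B
chr21	44589000	44592000	CRYAA
chr21	47608000	47648000	LSS
chr22	25598000	25608000	CRYBB3
chr22	25615000	25627000	CRYBB2
chr22	26995000	27014000	CRYBB1
chr22	27018000	27027000	CRYBA4
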