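ATF	1.0
8	6
"Type=GenePix Results 3"
"DateTime=2020/03/14 10:22:41"
"Settings="
"GalFile=prb_panel.gal"
"PixelSize=10"
"Wavelengths=635"
"ImageFiles=slide07.tif"
"NormalizationMethod=None"
"Block"	"Row"	"Column"	"ID"	"F635 Median"	"B635 Median"
1	1	1	"L1C1"	1520	88
1	1	2	"L1C1"	1480	90
1	1	3	"L1C1"	1505	91
1	2	1	"L6C1"	212	87
1	2	2	"L6C1"	196	86
1	2	3	"L6C1"	205	90
1	3	1	"P1"	95	89
1	3	2	"P1"	102	85
1	3	3	"P1"	99	88
1	4	1	"BSA"	91	90
1	4	2	"BSA"	97	84
1	4	3	"BSA"	104	92
1	5	1	"PPB"	89	87
1	5	2	"PPB"	100	88
1	5	3	"PPB"	93	85
1	6	1	"FRAME"	30012	90
1	6	2	"FRAME"	29870	86
1	6	3	"FRAME"	30240	91
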