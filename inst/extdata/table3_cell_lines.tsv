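cell_line	er	pr	her2	pam50_mrna	final_classification
AU565	-	-	+	Her2amp	Her2amp
BT-20	-	-	-	Basal-like	Basal-like
BT-474	+	+	+	Luminal B	Luminal B
BT-483	+	+	-	Luminal A	Luminal A
BT-549	-	-	-	Basal-like	Basal-like
CAL-120	-	-	-	Basal-like	Basal-like
CAL-148	-	-	-	Luminal B	Basal-like
CAL-51	-	-	-	Basal-like	Basal-like
CAL-85-1	-	-	-	Basal-like	Basal-like
CAMA-1	+	-	-	Luminal B	Luminal A
DU4475	-	-	-	Basal-like	Basal-like
EFM-19	+	+	-	Luminal B	Luminal A
EFM-192A	+	-	+	Her2amp	Luminal B
EVSA-T	+	-	+	NON	Luminal B
HCC1143	-	-	-	Basal-like	Basal-like
HCC1187	-	-	-	Basal-like	Basal-like
HCC1395	-	-	-	Basal-like	Basal-like
HCC1419	-	-	+	Her2amp	Her2amp
HCC1428	+	+	-	Luminal B	Luminal A
HCC1500	-	-	-	Luminal A	Basal-like
HCC1569	-	-	+	Basal-like	Her2amp
HCC1599	-	-	-	Basal-like	Basal-like
HCC1806	-	-	-	Basal-like	Basal-like
HCC1937	-	-	-	Basal-like	Basal-like
HCC1954	-	-	+	Her2amp	Her2amp
HCC202	-	-	+	Her2amp	Her2amp
HCC2157	-	-	-	Basal-like	Basal-like
HCC2218	-	-	+	Luminal A	Her2amp
HCC38	-	-	-	Basal-like	Basal-like
HCC70	-	-	-	Basal-like	Basal-like
HDQ-P1	-	-	-	Basal-like	Basal-like
HMC-1-8				NON	Luminal A
Hs 274.T				Basal-like	Luminal B
Hs 281.T				Basal-like	Her2amp
Hs 343.T				Basal-like	Her2amp
Hs 578 T	-	-	-	Basal-like	Basal-like
Hs 606.T				Luminal A	Luminal B
Hs 739.T				Basal-like	Basal-like
Hs 742.T				Luminal A	Luminal A
JIMT-1	-	-		Basal-like	Her2amp
KPL-1				Luminal A	Basal-like
MCF7	+	+	-	Luminal A	Luminal A
MDA-MB-134-VI	+	-		Luminal A	Luminal A
MDA-MB-157	-	-	-	Basal-like	Basal-like
MDA-MB-175-VII	+	-		Luminal B	Luminal A
MDA-MB-231	-	-		Basal-like	Basal-like
MDA-MB-361	+	+	+	Luminal B	Luminal B
MDA-MB-415	+	-	-	Luminal B	Luminal A
MDA-MB-436	-	-	-	Basal-like	Basal-like
MDA-MB-453	-	-	-	Luminal B	Her2amp
MDA-MB-468	-	-	-	Basal-like	Basal-like
SK-BR-3	-	-	+	Her2amp	Her2amp
T-47D	+	+	-	Luminal B	Luminal A
UACC-812	+	-	+	Her2amp	Luminal B
UACC-893	-	-	+	Her2amp	Her2amp
YMB-1	+	-	-	Luminal B	Luminal A
ZR-75-1				Luminal A	Her2amp
ZR-75-30	+	+	-	Her2amp	Luminal A
HCC2185	-	-	-	NON	Basal-like
HMEL				NON	Basal-like
HCC3153	-	-	-	NON	Basal-like
ZR75B	+	-	-	NON	Luminal A
600MPE	+	-	-	NON	Luminal A
SUM1315MO2	-	-		NON	Basal-like
SUM149PT	-	-	-	NON	Basal-like
SUM159PT	-	-	-	NON	Basal-like
SUM225CWN	-	-	+	NON	Her2amp
LY2	+	-	-	NON	Luminal A
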