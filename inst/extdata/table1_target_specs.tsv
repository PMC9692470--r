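biomarker	direction	disease
NFKB1	+	MIBC
MYC	+	MIBC
LEF1	+	MIBC
LEF1	+	ABC
MYC	+	ABC
FOXO1	-	ABC
NOTCH1	-	ABC
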