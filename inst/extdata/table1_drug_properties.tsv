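drug	target	regulation	sensitivity	lc50
Evodiamine	NFKB1	-0.453	-2.766	4.402
Embelin	NFKB1	-0.450	-0.563	5.223
Norethisterone	NFKB1	-0.448	0.325	2.946
Carbachol	NFKB1	-0.445	0.337	1.963
Zaleplon	NFKB1	-0.440	-1.522	3.324
Embelin	MYC	-0.822	-0.563	5.223
Dexrazoxane	MYC	-0.671	-1.558	3.004
Obatoclax	MYC	-0.539	-2.694	5.255
Roquinimex	MYC	-0.526	-1.831	4.524
Entinostat	MYC	-0.525	-1.013	4.971
Bortezomib	LEF1	-0.711	-5.840	2.474
Navitoclax	LEF1	-0.697	-0.913	3.97
Obatoclax	LEF1	-0.678	-2.694	5.255
Mitomycin-c	LEF1	-0.649	-1.269	3.017
Halofantrine	LEF1	-0.625	-1.604	6.478
Domperidone	FOXO1	0.268	-1.109	4.148
Mevastatin	FOXO1	0.262	-2.724	3.481
Ispinesib	FOXO1	0.252	-2.887	5.70
Entinostat	FOXO1	0.235	-1.013	4.971
Acebutolol	FOXO1	0.212	0.722	2.778
Tomelukast	NOTCH1	0.942	0.077	3.192
Imiquimod	NOTCH1	0.896	0.083	4.147
Quinelorane	NOTCH1	0.887	0.294	2.850
Mephenesin	NOTCH1	0.866	0.327	2.330
Celiprolol	NOTCH1	0.847	0.140	2.590
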