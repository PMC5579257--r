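drug	gene	interaction	source
celecoxib	MMP9	inhibition	curated
etoricoxib	BCAR1	decreased expression	curated
lumiracoxib	VEGFA	increased expression	curated
parecoxib	CACNA1E	binding	curated
rofecoxib	PTGS1	inhibition	curated
valdecoxib	PTGS2	decreased expression	curated
celecoxib	CA1	increased expression	curated
etoricoxib	CA2	binding	curated
lumiracoxib	CA4	inhibition	curated
parecoxib	CA5A	decreased expression	curated
rofecoxib	CA6	increased expression	curated
valdecoxib	CA7	binding	curated
celecoxib	CA9	inhibition	curated
etoricoxib	CA12	decreased expression	curated
lumiracoxib	CA13	increased expression	curated
parecoxib	CA14	binding	curated
rofecoxib	PDPK1	inhibition	curated
valdecoxib	AKT1	decreased expression	curated
celecoxib	CCND1	increased expression	curated
etoricoxib	CDKN1A	binding	curated
lumiracoxib	EGFR	inhibition	curated
parecoxib	ESR1	decreased expression	curated
rofecoxib	GSK3B	increased expression	curated
valdecoxib	HIF1A	binding	curated
celecoxib	IL6	inhibition	curated
etoricoxib	MAPK1	decreased expression	curated
lumiracoxib	MMP2	increased expression	curated
parecoxib	NFKB1	binding	curated
rofecoxib	NOS2	inhibition	curated
valdecoxib	PLA2G4A	decreased expression	curated
celecoxib	PPARG	increased expression	curated
etoricoxib	PTEN	binding	curated
lumiracoxib	RELA	inhibition	curated
parecoxib	SLC29A1	decreased expression	curated
rofecoxib	TNF	increased expression	curated
valdecoxib	TP53	binding	curated
celecoxib	TYMS	inhibition	curated
etoricoxib	ABCB1	decreased expression	curated
lumiracoxib	ABCG2	increased expression	curated
parecoxib	ALOX5	binding	curated
rofecoxib	CYP2C9	inhibition	curated
valdecoxib	CYP3A4	decreased expression	curated
celecoxib	DNMT1	increased expression	curated
etoricoxib	PGH2	binding	curated
lumiracoxib	PTGES-X	inhibition	curated
rofecoxib	PTGS2	inhibition	curated
valdecoxib	MMP9	decreased expression	curated
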