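gene	lead_snp	risk_allele	risk_freq	OR	p	p_combined	interaction	regulatory
BCAR1	rs4888383	T	0.57	1.05	7.99e-08	2.98e-08	inhibition	Promoter/Enhancer
MMP9	rs7270354	A	0.15	1.06	6.75e-08	3.34e-08	decreased expression	Promoter/Enhancer
VEGFA	rs6905288	A	0.6	1.04	7.44e-07	8.86e-07	decreased expression	Enhancer
CACNA1E	rs556321	C	0.16	1.05	8.26e-06	8.85e-06	inhibition	Promoter/Enhancer
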