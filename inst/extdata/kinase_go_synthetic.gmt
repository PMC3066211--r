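calmodulin binding	synthetic_annotation	SPHK1	PNCK	ITPKA	MYO3A	SYNK0001	SYNK0002	SYNK0003	SYNK0004	SYNK0005	SYNK0006	SYNK0007	SYNK0008	SYNK0009	SYNK0010	SYNK0011	SYNK0012	SYNK0013	SYNK0014	SYNK0015	SYNK0016	SYNK0017	SYNK0018	SYNK0019	SYNK0020	SYNK0021	SYNK0022	SYNK0023	SYNK0024	SYNK0025	SYNK0026	SYNK0027	SYNK0028	SYNK0029	SYNK0030	SYNK0031	SYNK0032	SYNK0033	SYNK0034	SYNK0035	SYNK0036	SYNK0037	SYNK0038	SYNK0039	SYNK0040	SYNK0041	SYNK0042	SYNK0043	SYNK0044	SYNK0045	SYNK0046	SYNK0047	SYNK0048	SYNK0049	SYNK0050	SYNK0051	SYNK0052	SYNK0053	SYNK0054	SYNK0055	SYNK0056	SYNK0057	SYNK0058	SYNK0059	SYNK0060	SYNK0061	SYNK0062	SYNK0063	SYNK0064	SYNK0065	SYNK0066	SYNK0067	SYNK0068	SYNK0069	SYNK0070	SYNK0071	SYNK0072	SYNK0073	SYNK0074	SYNK0075	SYNK0076	SYNK0077	SYNK0078	SYNK0079	SYNK0080	SYNK0081	SYNK0082	SYNK0083	SYNK0084	SYNK0085	SYNK0086	SYNK0087	SYNK0088	SYNK0089	SYNK0090	SYNK0091	SYNK0092	SYNK0093	SYNK0094	SYNK0095	SYNK0096	SYNK0097	SYNK0098	SYNK0099	SYNK0100	SYNK0101	SYNK0102	SYNK0103	SYNK0104	SYNK0105	SYNK0106	SYNK0107	SYNK0108	SYNK0109	SYNK0110	SYNK0111	SYNK0112	SYNK0113	SYNK0114	SYNK0115	SYNK0116	SYNK0117	SYNK0118	SYNK0119	SYNK0120	SYNK0121	SYNK0122	SYNK0123	SYNK0124	SYNK0125	SYNK0126	SYNK0127	SYNK0128	SYNK0129	SYNK0130	SYNK0131	SYNK0132	SYNK0133	SYNK0134	SYNK0135	SYNK0136
calmodulin-dependent protein kinase activity	synthetic_annotation	PNCK	ITPKA	SYNK0137	SYNK0138	SYNK0139	SYNK0140	SYNK0141	SYNK0142	SYNK0143	SYNK0144	SYNK0145	SYNK0146	SYNK0147	SYNK0148
inositol trisphosphate 3-kinase activity	synthetic_annotation	IPMK	ITPKA	SYNK0149	SYNK0150	SYNK0151	SYNK0152	SYNK0153
uridine kinase activity	synthetic_annotation	UCK1	SYNK0154	SYNK0155	SYNK0156
nucleoside triphosphate adenylate kinase activity	synthetic_annotation	AK3
phosphomevalonate kinase activity	synthetic_annotation	PMVK
pantetheine-phosphate adenylyltransferase activity	synthetic_annotation	COASY
D-erythro-sphingosine kinase activity	synthetic_annotation	SPHK1
plus-end directed microfilament motor activity	synthetic_annotation	MYO3A
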