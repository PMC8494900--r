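cell	type
cell0001	1
cell0002	1
cell0003	1
cell0004	1
cell0005	2
cell0006	2
cell0007	2
cell0008	2
cell0009	1
cell0010	2
cell0011	1
cell0012	1
cell0013	1
cell0014	1
cell0015	2
cell0016	2
cell0017	2
cell0018	1
cell0019	1
cell0020	2
cell0021	1
cell0022	1
cell0023	2
cell0024	1
cell0025	1
cell0026	1
cell0027	2
cell0028	2
cell0029	2
cell0030	1
cell0031	2
cell0032	2
cell0033	2
cell0034	1
cell0035	1
cell0036	1
cell0037	2
cell0038	2
cell0039	2
cell0040	2
cell0041	2
cell0042	1
cell0043	1
cell0044	1
cell0045	2
cell0046	1
cell0047	2
cell0048	2
cell0049	2
cell0050	2
cell0051	1
cell0052	1
cell0053	2
cell0054	2
cell0055	2
cell0056	2
cell0057	1
cell0058	1
cell0059	1
cell0060	1
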