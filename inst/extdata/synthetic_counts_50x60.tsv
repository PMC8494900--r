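gene	cell0001	cell0002	cell0003	cell0004	cell0005	cell0006	cell0007	cell0008	cell0009	cell0010	cell0011	cell0012	cell0013	cell0014	cell0015	cell0016	cell0017	cell0018	cell0019	cell0020	cell0021	cell0022	cell0023	cell0024	cell0025	cell0026	cell0027	cell0028	cell0029	cell0030	cell0031	cell0032	cell0033	cell0034	cell0035	cell0036	cell0037	cell0038	cell0039	cell0040	cell0041	cell0042	cell0043	cell0044	cell0045	cell0046	cell0047	cell0048	cell0049	cell0050	cell0051	cell0052	cell0053	cell0054	cell0055	cell0056	cell0057	cell0058	cell0059	cell0060
gene0001	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
gene0002	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0	2	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0
gene0003	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0
gene0004	0	0	0	0	0	0	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0
gene0005	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	2	1	0	0	0	0	0	1	0	0	0	0	0	1	0	0	1	0	1	1	0	0	0	0	0	0	0	0	2	0	1	1	0	0	1	0	0	0	2	0	0	0	0	0
gene0006	0	1	0	0	0	0	5	3	0	1	1	1	1	0	9	2	3	0	1	0	0	0	1	0	1	0	5	4	4	1	0	6	3	0	1	1	1	2	11	6	3	0	0	0	7	0	3	4	2	11	0	0	2	3	2	6	0	1	0	0
gene0007	0	0	0	0	1	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	2	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
gene0008	0	0	0	0	1	3	1	0	0	0	1	2	5	2	0	2	0	0	1	2	1	4	0	0	0	0	0	2	3	0	0	0	1	0	0	4	0	1	1	0	1	0	1	0	0	1	0	0	2	0	0	0	1	1	2	0	0	0	0	2
gene0009	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	0	1	0	0	0	1	0	0	0	0	0
gene0010	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
gene0011	0	0	0	1	0	0	1	0	0	1	1	0	1	0	0	1	0	1	0	0	0	0	1	0	0	1	5	1	0	1	0	0	0	1	0	0	0	2	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	3	2
gene0012	0	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0
gene0013	1	0	2	2	0	2	3	1	4	0	0	0	0	0	2	0	2	3	2	1	2	0	0	0	1	1	1	0	1	0	1	3	2	2	2	0	1	0	1	1	1	1	0	1	2	1	0	1	0	1	1	1	2	1	5	0	1	0	2	0
gene0014	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	1	0	0	0	0	0	0	0	0	0	1	1	0	0	0	1	0	0	1	2	1	1	0	0	0	0	0	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	2
gene0015	0	1	0	1	0	0	0	2	0	2	1	0	1	0	0	0	1	3	2	0	1	0	1	0	0	0	2	0	0	0	1	0	0	1	1	0	2	0	0	0	0	4	1	0	1	0	1	1	2	0	0	0	0	0	0	0	3	0	1	0
gene0016	7	0	9	7	0	0	1	0	3	0	1	3	3	0	1	0	0	5	4	1	1	3	1	2	0	2	0	0	0	3	1	1	1	4	2	0	0	0	0	0	0	4	1	4	0	3	0	0	1	0	8	2	0	0	0	0	2	1	1	7
gene0017	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	2	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
gene0018	1	2	4	3	1	0	4	2	0	0	1	3	2	3	0	1	3	2	1	3	1	0	2	2	1	5	1	2	2	0	1	1	0	2	2	0	0	2	3	3	2	1	2	2	5	0	0	0	0	0	2	0	0	5	2	5	1	1	1	0
gene0019	0	1	1	1	1	3	0	0	0	0	0	0	0	0	0	2	0	0	0	0	1	2	0	0	1	0	0	0	0	1	1	0	0	0	0	1	0	1	0	0	1	0	0	0	0	0	0	0	1	2	1	1	2	2	1	0	0	0	0	0
gene0020	0	0	0	0	0	2	1	0	0	0	0	0	1	0	0	1	1	0	0	1	0	1	1	2	1	0	1	1	0	0	0	0	0	0	0	1	0	0	1	0	1	0	0	2	1	2	0	0	0	1	0	0	0	0	1	0	0	0	0	0
gene0021	1	0	0	0	2	0	1	2	3	0	0	0	0	0	0	0	0	0	0	0	0	0	1	3	3	3	0	0	3	1	0	1	0	0	0	0	0	1	0	0	2	0	0	0	0	0	1	2	0	0	0	0	1	2	0	1	0	0	2	0
gene0022	0	0	1	0	3	6	5	7	2	18	0	1	2	2	1	3	3	0	3	6	0	0	4	0	2	0	7	2	10	0	2	7	5	0	2	0	1	15	4	1	1	1	0	1	2	1	2	7	1	0	0	2	5	2	4	4	3	0	2	0
gene0023	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	0	1	0	0	0	0	0	1	1	2	0	1	0	1	0	0	0	0	0	1	0	0	1	1	0	2	1	2	0	0	0	0	0	1	0	0	0	2
gene0024	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
gene0025	1	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	2	2	1	0	0	1	0	2	1	0	0	0	0	0	0	1	1	0	1	1	0	0	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	1	1	1	0	1	2	0
gene0026	0	0	1	0	1	0	1	0	0	1	0	0	0	0	0	1	0	0	1	0	1	0	1	0	0	0	0	0	0	0	0	0	2	1	0	0	0	1	0	1	0	0	1	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0
gene0027	0	0	0	0	0	0	0	0	2	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	1	1	0	0	1	0	0	0	0	1	0	0	0	1	1	1	0	1	0	0	1	0	0	0	0	0	0	0	1	0	0	0
gene0028	3	1	0	2	0	1	1	0	1	2	0	2	3	0	1	1	0	2	0	0	0	1	0	0	0	0	0	1	0	0	3	0	2	0	0	0	0	1	1	1	1	0	0	0	1	1	1	0	0	0	3	0	0	1	0	0	0	1	0	1
gene0029	0	1	2	0	0	0	1	0	0	1	1	0	2	6	1	1	0	6	2	1	0	0	0	1	1	1	4	1	2	0	3	0	0	3	3	0	0	3	1	2	0	0	0	0	3	2	0	2	3	1	1	0	3	4	0	1	0	1	1	0
gene0030	2	0	1	0	0	0	0	0	2	0	2	2	0	1	1	0	0	2	0	0	2	1	0	0	1	5	1	0	1	0	0	0	3	0	1	1	0	0	0	0	0	2	3	0	0	0	0	0	0	0	2	1	0	0	0	0	0	1	1	0
gene0031	1	16	14	23	0	0	0	0	12	2	5	18	12	37	0	1	0	17	4	4	6	6	1	16	1	14	2	1	0	11	0	1	0	10	17	3	2	2	0	1	3	0	15	0	0	6	1	1	1	0	20	4	0	0	4	0	5	11	3	2
gene0032	0	1	0	0	5	2	3	3	0	1	1	0	2	0	3	6	5	2	0	17	0	2	8	0	0	1	3	0	8	2	6	5	7	0	0	0	1	16	1	6	7	1	1	0	11	0	3	2	0	5	1	0	6	0	2	2	1	1	1	1
gene0033	1	0	1	0	0	4	0	2	1	1	0	1	3	2	0	0	1	1	1	0	0	1	0	0	0	0	1	0	1	1	1	1	2	0	2	0	0	0	1	1	1	1	1	2	0	0	0	1	0	0	0	1	0	0	1	2	0	1	2	1
gene0034	2	1	5	1	0	3	1	0	15	2	15	1	6	3	0	0	1	12	10	2	2	5	0	4	4	10	0	0	0	7	3	2	0	9	1	7	3	1	0	1	0	7	8	4	3	6	0	1	0	0	4	1	0	0	2	0	6	2	4	4
gene0035	3	0	1	1	0	0	0	2	1	0	2	2	2	0	1	0	0	0	1	0	0	1	0	1	1	0	0	0	0	0	3	0	2	0	1	0	1	0	0	0	3	2	0	1	1	0	0	2	1	0	0	2	2	0	0	2	0	0	2	0
gene0036	0	0	0	0	0	0	0	0	2	0	0	2	1	1	0	0	0	0	0	0	0	0	0	0	1	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
gene0037	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	1	0	1	0	1	1	1	0	0	0	0	0	0	0	0	0	0	2	0	1	1	0	0	0	0	0	0
gene0038	0	1	1	2	0	5	11	3	3	1	0	0	0	0	3	2	0	1	0	4	1	0	5	1	1	0	3	2	3	2	5	4	9	0	0	0	6	7	7	6	3	0	1	0	5	1	6	3	0	1	0	0	6	1	7	1	2	0	0	0
gene0039	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	2	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	1	1	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
gene0040	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	0	0	1	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	1	0	0	2	0	0	0	0
gene0041	1	0	0	0	1	1	0	0	1	1	0	0	3	1	1	0	1	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	1	0	2	1	1	0	2	0	1	0	1	0	0	0	0	0	2	0	1	0	0	2	0	0	0	2	0
gene0042	0	2	0	0	2	1	0	1	0	0	1	0	1	0	0	0	0	0	1	0	0	0	0	2	0	0	0	1	2	2	3	0	0	0	1	4	0	1	0	0	1	1	0	0	0	2	0	1	0	4	0	1	0	0	1	0	2	0	1	0
gene0043	1	1	0	0	2	0	1	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	1	0	0	0	2	2	1	0	0	1	0	2	1	0	1	0	1	0	1	0	0	1	0	1	1	1	0	0	0	0	0	1	0	0	0	0	0	0
gene0044	0	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
gene0045	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1
gene0046	0	0	2	0	0	0	3	2	1	1	1	3	0	0	3	3	0	3	2	2	5	1	0	0	3	2	0	1	2	1	1	2	0	2	0	1	0	2	2	3	4	2	3	1	0	0	0	2	1	1	2	0	2	5	0	0	2	1	0	4
gene0047	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0	0	0	0	0	3	1	0	0	2	0	2	1	0	0	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	1	0	0	0	2	1	0	0	0	1
gene0048	0	0	2	0	12	2	3	2	0	1	1	0	1	0	2	0	0	0	0	1	0	2	4	1	0	0	9	0	7	0	5	7	3	0	0	0	3	2	0	0	0	0	1	1	3	0	5	0	5	2	0	1	2	0	1	1	0	1	1	1
gene0049	7	3	2	0	1	0	0	0	3	0	3	3	2	1	1	0	0	2	1	0	0	2	0	1	3	3	0	0	0	2	0	0	2	6	10	0	1	0	0	0	0	1	0	8	0	5	0	0	0	1	0	7	1	0	0	0	5	1	1	2
gene0050	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	0
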