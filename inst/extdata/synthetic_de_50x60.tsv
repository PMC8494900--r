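gene	de	type
gene0001	FALSE	NA
gene0002	FALSE	NA
gene0003	FALSE	NA
gene0004	FALSE	NA
gene0005	FALSE	NA
gene0006	TRUE	2
gene0007	FALSE	NA
gene0008	FALSE	NA
gene0009	FALSE	NA
gene0010	FALSE	NA
gene0011	FALSE	NA
gene0012	FALSE	NA
gene0013	FALSE	NA
gene0014	FALSE	NA
gene0015	FALSE	NA
gene0016	TRUE	1
gene0017	FALSE	NA
gene0018	FALSE	NA
gene0019	FALSE	NA
gene0020	FALSE	NA
gene0021	FALSE	NA
gene0022	TRUE	2
gene0023	FALSE	NA
gene0024	FALSE	NA
gene0025	FALSE	NA
gene0026	FALSE	NA
gene0027	FALSE	NA
gene0028	FALSE	NA
gene0029	FALSE	NA
gene0030	TRUE	1
gene0031	TRUE	1
gene0032	TRUE	2
gene0033	FALSE	NA
gene0034	TRUE	1
gene0035	FALSE	NA
gene0036	FALSE	NA
gene0037	FALSE	NA
gene0038	TRUE	2
gene0039	FALSE	NA
gene0040	FALSE	NA
gene0041	FALSE	NA
gene0042	FALSE	NA
gene0043	FALSE	NA
gene0044	FALSE	NA
gene0045	FALSE	NA
gene0046	FALSE	NA
gene0047	FALSE	NA
gene0048	TRUE	2
gene0049	TRUE	1
gene0050	FALSE	NA
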