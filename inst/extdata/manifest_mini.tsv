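probe_id	design	channel	address_U	address_M	chromosome	probe_class
cg000001	I	Grn	A001	A002	1	cg
cg000002	I	Grn	A003	A004	chr2	cg
cg000003	I	Red	A005	A006	X	cg
cg000004	I	Red	A007	A008	chrY	cg
cg000005	II	NA	A009	A009	7	cg
neg00001	II	NA	A010	A010	NA	negative_control
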