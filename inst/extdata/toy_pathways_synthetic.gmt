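sphingolipid_metabolism	synthetic demonstration membership, not a curated pathway	mRNA_0001	mRNA_0002	mRNA_0003	mRNA_0004	mRNA_0005	mRNA_0006	mRNA_0007	mRNA_0008	mRNA_0009	mRNA_0010	mRNA_0011	mRNA_0012	mRNA_0013	mRNA_0014	mRNA_0015	mRNA_0016	mRNA_0017	mRNA_0018	mRNA_0019	mRNA_0020
glutathione_metabolism	synthetic demonstration membership, not a curated pathway	mRNA_0041	mRNA_0042	mRNA_0043	mRNA_0044	mRNA_0045	mRNA_0046	mRNA_0047	mRNA_0048	mRNA_0049	mRNA_0050	mRNA_0051	mRNA_0052	mRNA_0053	mRNA_0054	mRNA_0055
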