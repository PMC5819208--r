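snp_id	gene	chrom	ea	ra	eaf	beta_NP	se_NP	p_NP	beta_NFT	se_NFT	p_NFT	beta_CAA	se_CAA	p_CAA	p_joint_NP_NFT	p_joint_NP_CAA	p_joint_NFT_CAA
rs34487851	C2orf40	2	G	A	0.27	-0.30	0.06	7.7e-7	-0.25	0.06	4.5e-6	-0.14	0.08	0.06	2.0e-8	2.5e-6	2.1e-5
rs79524815	HDAC9	7	G	T	0.03	0.43	0.19	0.03	0.79	0.19	2.3e-5	1.16	0.26	9.1e-6	1.3e-4	3.3e-6	1.1e-8
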