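probe_id	gene_id
200001_at	GENE_A
200002_s_at	GENE_A
200003_at	GENE_B
200004_x_at	GENE_C
200005_at	GENE_D
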