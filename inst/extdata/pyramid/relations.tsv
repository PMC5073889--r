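label	category	relation
PBMC	T cells	mixed
PBMC	CD4 T cells	mixed
PBMC	CD8 T cells	mixed
PBMC	Effector memory CD8 T cells	mixed
PBMC	Cytotoxic lymphocytes	mixed
PBMC	NK cells	mixed
PBMC	B lineage	mixed
PBMC	B cells	mixed
PBMC	Monocytic lineage	mixed
PBMC	Monocytes	mixed
PBMC	Myeloid dendritic cells	mixed
T cells	CD8 T cells	mixed
T cells	CD4 T cells	mixed
T cells	Effector memory CD8 T cells	mixed
T cells	Cytotoxic lymphocytes	mixed
CD8 T cells	Effector memory CD8 T cells	mixed
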