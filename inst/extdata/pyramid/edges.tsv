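child	parent
CD4 T cells	T cells
CD8 T cells	T cells
Effector memory CD8 T cells	CD8 T cells
CD8 T cells	Cytotoxic lymphocytes
NK cells	Cytotoxic lymphocytes
B cells	B lineage
Plasma cells	B lineage
Monocytes	Monocytic lineage
Macrophages	Monocytic lineage
T cells	Microenvironment
Cytotoxic lymphocytes	Microenvironment
B lineage	Microenvironment
Monocytic lineage	Microenvironment
Myeloid dendritic cells	Microenvironment
Neutrophils	Microenvironment
Endothelial cells	Microenvironment
Fibroblasts	Microenvironment
PBMC	Microenvironment
Tumor cell line	Microenvironment
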