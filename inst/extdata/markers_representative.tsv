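population	feature	namespace
T cells	CD3D	hugo_symbol
T cells	CD5	hugo_symbol
CD8 T cells	CD8B	hugo_symbol
Cytotoxic lymphocytes	EOMES	hugo_symbol
Cytotoxic lymphocytes	GNLY	hugo_symbol
NK cells	NCR1	hugo_symbol
NK cells	KIR2DL3	hugo_symbol
B lineage	CD19	hugo_symbol
B lineage	CD79A	hugo_symbol
B lineage	CD79B	hugo_symbol
Monocytic lineage	CSF1R	hugo_symbol
Myeloid dendritic cells	CD1A	hugo_symbol
Myeloid dendritic cells	CD1B	hugo_symbol
Myeloid dendritic cells	CD1E	hugo_symbol
Neutrophils	FCGR3B	hugo_symbol
Neutrophils	CEACAM3	hugo_symbol
Endothelial cells	VWF	hugo_symbol
Endothelial cells	CDH5	hugo_symbol
Fibroblasts	DCN	hugo_symbol
Fibroblasts	TAGLN	hugo_symbol
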