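node	is_label	screenable
Microenvironment	FALSE	FALSE
T cells	TRUE	TRUE
CD4 T cells	TRUE	TRUE
CD8 T cells	TRUE	TRUE
Effector memory CD8 T cells	TRUE	TRUE
Cytotoxic lymphocytes	FALSE	TRUE
NK cells	TRUE	TRUE
B cells	TRUE	TRUE
Plasma cells	TRUE	TRUE
B lineage	FALSE	TRUE
Monocytes	TRUE	TRUE
Macrophages	TRUE	TRUE
Monocytic lineage	FALSE	TRUE
Myeloid dendritic cells	TRUE	TRUE
Neutrophils	TRUE	TRUE
Endothelial cells	TRUE	TRUE
Fibroblasts	TRUE	TRUE
PBMC	TRUE	FALSE
Tumor cell line	TRUE	FALSE
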