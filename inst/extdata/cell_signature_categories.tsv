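B-cells	lymphoid
Naive B-cells	lymphoid
Memory B-cells	lymphoid
Class-switched memory B-cells	lymphoid
pro-B cells	lymphoid
Plasma cells	lymphoid
CD4+ T-cells	lymphoid
CD4+ naive T-cells	lymphoid
CD4+ memory T-cells	lymphoid
CD4+ Tcm	lymphoid
CD4+ Tem	lymphoid
CD8+ T-cells	lymphoid
CD8+ naive T-cells	lymphoid
CD8+ Tcm	lymphoid
CD8+ Tem	lymphoid
Tregs	lymphoid
Th1 cells	lymphoid
Th2 cells	lymphoid
Th17 cells	lymphoid
Tfh cells	lymphoid
T helper cells	lymphoid
Tgd cells	lymphoid
NK cells	lymphoid
NKT cells	lymphoid
CD56bright NK cells	lymphoid
CD56dim NK cells	lymphoid
Cytotoxic T-cells	lymphoid
Effector T-cells	lymphoid
Exhausted CD8+ T-cells	lymphoid
MAIT cells	lymphoid
Germinal center B-cells	lymphoid
Immature B-cells	lymphoid
Activated B-cells	lymphoid
Activated CD4+ T-cells	lymphoid
Activated CD8+ T-cells	lymphoid
Central memory T-cells	lymphoid
Effector memory T-cells	lymphoid
Follicular B-cells	lymphoid
Marginal zone B-cells	lymphoid
Innate lymphoid cells	lymphoid
Monocytes	myeloid
Classical monocytes	myeloid
Non-classical monocytes	myeloid
Macrophages	myeloid
Macrophages M1	myeloid
Macrophages M2	myeloid
Dendritic cells	myeloid
Conventional dendritic cells	myeloid
Plasmacytoid dendritic cells	myeloid
Activated dendritic cells	myeloid
Immature dendritic cells	myeloid
Neutrophils	myeloid
Eosinophils	myeloid
Basophils	myeloid
Mast cells	myeloid
Hematopoietic stem cells	stem
Common lymphoid progenitors	stem
Common myeloid progenitors	stem
Granulocyte-macrophage progenitors	stem
Megakaryocyte-erythroid progenitors	stem
Multipotent progenitors	stem
Megakaryocytes	stem
Erythrocytes	stem
Platelets	stem
Mesenchymal stem cells	stem
Endothelial progenitor cells	stem
Endothelial cells	stromal
Lymphatic endothelial cells	stromal
Microvascular endothelial cells	stromal
Fibroblasts	stromal
Pericytes	stromal
Smooth muscle cells	stromal
Skeletal muscle cells	stromal
Myocytes	stromal
Adipocytes	stromal
Chondrocytes	stromal
Osteoblasts	stromal
Epithelial cells	other
Keratinocytes	other
Sebocytes	other
Hepatocytes	other
Melanocytes	other
Mesangial cells	other
Neurons	other
Astrocytes	other
Basal cells	other
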