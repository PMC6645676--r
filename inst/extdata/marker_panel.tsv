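cell_type	gene
smooth_muscle	MCAM
smooth_muscle	DES
endothelial	TJP1
endothelial	SLC2A1
endothelial	VCAM1
endothelial	SELE
endothelial	VWF
macrophage	CD14
macrophage	FCGR1A
macrophage	CD68
macrophage	TFRC
macrophage	CCR5
mast_cell	KIT
mast_cell	ENPP3
t_cell	CD3D
t_cell	CD3E
t_cell	CD3G
t_cell	CD4
t_cell	CD8A
t_cell	CD8B
t_cell	IL2RA
t_cell	IL7R
t_cell	CCR6
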