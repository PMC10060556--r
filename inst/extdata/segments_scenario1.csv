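name,proximal_node,distal_node,length_cm,radius_cm,E_MPa,h_rel,law,provenance
asc_aorta,root,j1,4.0,1.20,0.4,0.10,aorta,classic 0D/1D systemic-tree anatomy; male adult
aortic_arch_1,j1,j2,2.0,1.12,0.4,0.10,aorta,classic 0D/1D systemic-tree anatomy; male adult
aortic_arch_2,j2,j3,3.9,1.07,0.4,0.10,aorta,classic 0D/1D systemic-tree anatomy; male adult
brachiocephalic,j1,bc,3.4,0.62,0.4,0.12,none,classic 0D/1D systemic-tree anatomy; male adult
cca_r,bc,cca_r_e,17.7,0.25,0.8,0.15,cca,classic 0D/1D systemic-tree anatomy; male adult
cca_l,j2,cca_l_e,20.8,0.25,0.8,0.15,cca,classic 0D/1D systemic-tree anatomy; male adult
subclavian_r,bc,sub_r_e,3.4,0.423,0.8,0.12,none,classic 0D/1D systemic-tree anatomy; male adult
subclavian_l,j3,sub_l_e,3.4,0.423,0.8,0.12,none,classic 0D/1D systemic-tree anatomy; male adult
vertebral_r,sub_r_e,bas_j,14.8,0.165,0.8,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
vertebral_l,sub_l_e,bas_j,14.8,0.165,0.8,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
ica_1_r,cca_r_e,ica_m_r,11.8,0.20,0.8,0.15,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
ica_1_l,cca_l_e,ica_m_l,11.8,0.20,0.8,0.15,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
ica_2_r,ica_m_r,ica_e_r,5.9,0.20,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
ica_2_l,ica_m_l,ica_e_l,5.9,0.20,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
basilar,bas_j,bas_e,2.9,0.162,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
pca_1_r,bas_e,pca_j_r,0.5,0.107,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
pca_1_l,bas_e,pca_j_l,0.5,0.107,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
pcoa_r,ica_e_r,pca_j_r,1.5,0.125,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
pcoa_l,ica_e_l,pca_j_l,1.5,0.125,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
aca_1_r,ica_e_r,aca_j_r,1.2,0.117,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
aca_1_l,ica_e_l,aca_j_l,1.2,0.117,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
acoa,aca_j_l,aca_j_r,0.3,0.074,1.6,0.20,none,cerebral 0D/1D circle-of-Willis anatomy; communicating/vertebral calibre calibrated
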