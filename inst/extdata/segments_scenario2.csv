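name,proximal_node,distal_node,length_cm,radius_cm,E_MPa,h_rel,law,provenance
asc_aorta,root,j1,4.320,1.128,0.4,0.10,aorta,alternative source anatomy; lengths +8% radii -6%
aortic_arch_1,j1,j2,2.160,1.053,0.4,0.10,aorta,alternative source anatomy; lengths +8% radii -6%
aortic_arch_2,j2,j3,4.212,1.006,0.4,0.10,aorta,alternative source anatomy; lengths +8% radii -6%
brachiocephalic,j1,bc,3.672,0.583,0.4,0.12,none,alternative source anatomy; lengths +8% radii -6%
cca_r,bc,cca_r_e,19.116,0.235,0.8,0.15,cca,alternative source anatomy; lengths +8% radii -6%
cca_l,j2,cca_l_e,22.464,0.235,0.8,0.15,cca,alternative source anatomy; lengths +8% radii -6%
subclavian_r,bc,sub_r_e,3.672,0.398,0.8,0.12,none,alternative source anatomy; lengths +8% radii -6%
subclavian_l,j3,sub_l_e,3.672,0.398,0.8,0.12,none,alternative source anatomy; lengths +8% radii -6%
vertebral_r,sub_r_e,bas_j,15.984,0.155,0.8,0.20,none,alternative source anatomy; lengths +8% radii -6%
vertebral_l,sub_l_e,bas_j,15.984,0.155,0.8,0.20,none,alternative source anatomy; lengths +8% radii -6%
ica_1_r,cca_r_e,ica_m_r,12.744,0.188,0.8,0.15,none,alternative source anatomy; lengths +8% radii -6%
ica_1_l,cca_l_e,ica_m_l,12.744,0.188,0.8,0.15,none,alternative source anatomy; lengths +8% radii -6%
ica_2_r,ica_m_r,ica_e_r,6.372,0.188,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
ica_2_l,ica_m_l,ica_e_l,6.372,0.188,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
basilar,bas_j,bas_e,3.132,0.152,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
pca_1_r,bas_e,pca_j_r,0.540,0.101,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
pca_1_l,bas_e,pca_j_l,0.540,0.101,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
pcoa_r,ica_e_r,pca_j_r,1.620,0.117,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
pcoa_l,ica_e_l,pca_j_l,1.620,0.117,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
aca_1_r,ica_e_r,aca_j_r,1.296,0.110,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
aca_1_l,ica_e_l,aca_j_l,1.296,0.110,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
acoa,aca_j_l,aca_j_r,0.324,0.070,1.6,0.20,none,alternative source anatomy; lengths +8% radii -6%
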