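name,artery_node,territory,R_total_mmHg_s_ml,rp_frac,tau_s,reference,provenance
thoracic_aorta,j3,thoracic_aorta,1.322,0.2,1.3,venous_source,alternative source anatomy; terminal resistances +12%
brachial_r,sub_r_e,brachial-R,31.360,0.2,1.3,venous_source,alternative source anatomy; terminal resistances +12%
brachial_l,sub_l_e,brachial-L,31.360,0.2,1.3,venous_source,alternative source anatomy; terminal resistances +12%
eca_r,cca_r_e,ECA-R,28.000,0.2,1.3,venous_source,alternative source anatomy; terminal resistances +12%
eca_l,cca_l_e,ECA-L,28.000,0.2,1.3,venous_source,alternative source anatomy; terminal resistances +12%
mca_r,ica_e_r,MCA-R,73.920,0.3,2.5,icp_coupled,alternative source anatomy; terminal resistances +12%
mca_l,ica_e_l,MCA-L,73.920,0.3,2.5,icp_coupled,alternative source anatomy; terminal resistances +12%
aca_r,aca_j_r,ACA-R,69.440,0.3,0.9,icp_coupled,alternative source anatomy; terminal resistances +12%
aca_l,aca_j_l,ACA-L,69.440,0.3,0.9,icp_coupled,alternative source anatomy; terminal resistances +12%
pca_r,pca_j_r,PCA-R,89.600,0.3,0.42,icp_coupled,alternative source anatomy; terminal resistances +12%
pca_l,pca_j_l,PCA-L,89.600,0.3,0.42,icp_coupled,alternative source anatomy; terminal resistances +12%
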