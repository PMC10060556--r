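name,artery_node,territory,R_total_mmHg_s_ml,rp_frac,tau_s,reference,provenance
thoracic_aorta,j3,thoracic_aorta,1.18,0.2,1.3,venous_source,sized for ~72 ml/s descending-aorta flow at MAP ~90 mmHg
brachial_r,sub_r_e,brachial-R,28,0.2,1.3,venous_source,sized for ~3 ml/s arm flow
brachial_l,sub_l_e,brachial-L,28,0.2,1.3,venous_source,sized for ~3 ml/s arm flow
eca_r,cca_r_e,ECA-R,25,0.2,1.3,venous_source,sized for ~3.4 ml/s external-carotid flow
eca_l,cca_l_e,ECA-L,25,0.2,1.3,venous_source,sized for ~3.4 ml/s external-carotid flow
mca_r,ica_e_r,MCA-R,66,0.3,2.5,icp_coupled,largest cerebral territory ~2.2 ml/s; most compliant bed
mca_l,ica_e_l,MCA-L,66,0.3,2.5,icp_coupled,largest cerebral territory ~2.2 ml/s; most compliant bed
aca_r,aca_j_r,ACA-R,62,0.3,0.9,icp_coupled,anterior territory ~1.4 ml/s
aca_l,aca_j_l,ACA-L,62,0.3,0.9,icp_coupled,anterior territory ~1.4 ml/s
pca_r,pca_j_r,PCA-R,80,0.3,0.42,icp_coupled,posterior territory ~1.1 ml/s
pca_l,pca_j_l,PCA-L,80,0.3,0.42,icp_coupled,posterior territory ~1.1 ml/s
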