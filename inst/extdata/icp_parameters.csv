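name,value,unit,provenance
R_couple,3.0,mmHg_s_ml,per-trunk tap from distal ICA / basilar nodes into the intracranial bed; calibrated
R1_1,2.5,mmHg_s_ml,proximal arterial cerebrovascular bed; calibrated
R1_2,1.5,mmHg_s_ml,proximal arterial cerebrovascular bed; calibrated
Ci_1,0.006,ml_mmHg,proximal arterial bed compliance (transmural to ICP); calibrated
R2_1,1.0,mmHg_s_ml,distal arterial cerebrovascular bed; calibrated
R2_2,1.0,mmHg_s_ml,distal arterial cerebrovascular bed; calibrated
Ci_2,0.022,ml_mmHg,distal arterial bed compliance (transmural to ICP); calibrated
Cvi,0.05,ml_mmHg,intracranial venous compliance (transmural to ICP); calibrated
Rpv,6.5,mmHg_s_ml,proximal venous cerebrovascular bed; calibrated
Rdv,0.8,mmHg_s_ml,distal venous bed (lateral lacunae and bridge veins)
Rve,0.37,mmHg_s_ml,extracranial venous pathway
Cue,1.0,ml_mmHg,extracranial venous compliance
Rf,73,mmHg_s_ml,CSF formation resistance; calibrated
Ro,22,mmHg_s_ml,CSF outflow resistance; calibrated
Pcv,5,mmHg,central venous pressure
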