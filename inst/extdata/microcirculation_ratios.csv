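key,value
r_arteriole,0.55
r_capillary,0.25
r_venule,0.20
c_capillary_frac,0.20
rava_multiplier,10
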