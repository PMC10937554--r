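representation,load_type,init_median_deg,init_iqr_deg,init_pct,opt_median_deg,opt_iqr_deg,opt_pct
uniform,lb,2.0,0.9,30,1.1,1.3,16
uniform,ar,0.6,0.1,27,0.5,0.2,24
uniform,fe,3.2,1.6,44,1.2,0.7,17
level_dependent,lb,16.5,1.7,247,1.6,0.6,25
level_dependent,ar,1.0,0.3,38,0.9,0.4,33
level_dependent,fe,5.3,1.6,75,2.4,0.9,33
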