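stenosis_pct,dP_rest_mmHg,ffr_rest,ffr_rest_clamped,dP_hyper_mmHg,ffr_hyper,ffr_hyper_clamped,dP_rest_sigfigs,dP_hyper_sigfigs,unit_suspect_hyper
0,0.40,0.996,FALSE,1.19,0.988,FALSE,2,3,FALSE
25,0.76,0.992,FALSE,3.18,0.968,FALSE,2,3,FALSE
50,12.91,0.871,FALSE,107.47,0.0,TRUE,4,5,FALSE
75,4600,0.0,TRUE,5510000,0.0,TRUE,3,3,TRUE
90,7800000,0.0,TRUE,9360000000,0.0,TRUE,3,3,TRUE
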