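material,center_cm1,strength,damping_cm1,eps_inf_real,eps_inf_imag
si,NA,NA,NA,11.7,0
d2o,NA,NA,NA,1.69,0.35
sin,980,3.0,80,4.0,0
lipid_trans,1466,0.0020,20,2.1,0
lipid_trans,1496,0.0015,18,2.1,0
lipid_trans,1603,0.0040,25,2.1,0
lipid_trans,1740,0.0075,30,2.1,0
lipid_cis,1466,0.0015,20,2.1,0
lipid_cis,1496,0.0010,18,2.1,0
lipid_cis,1603,0.0015,25,2.1,0
lipid_cis,1740,0.0075,30,2.1,0
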