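substituent,position,sigma_p,sigma_p_plus
OCH3,para,-0.27,-0.78
CH3,para,-0.17,-0.31
H,para,0,0
F,para,0.06,-0.07
Cl,para,0.23,0.11
CF3,para,0.54,0.61
CN,para,0.66,0.66
NO2,para,0.78,0.79
NH2,C3,,-1.30
NHCH3,C3,,-1.81
N(CH3)2,C3,,-1.70
OCH3,C3,,-0.78
CH3,C3,,-0.31
H,C3,,0
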