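name,sigma_plus_C3,k_ref,E_ref,N,N_exp,s_N
3-Aminothiophene,-1.30,3.37e4,-5.06,9.59,9.37,1
3-(Methylamino)thiophene,-1.81,2.58e5,-5.06,10.47,10.47,1
3-(Dimethylamino)thiophene,-1.70,9.03e4,-5.06,10.02,10.02,1
"1,2,3-Trimethylpyrrole",,2.40e4,-5.06,9.44,,1
N-Methylpyrrole,,1.00e2,-5.06,7.06,,1
N-Methylindole,,3.51e3,-5.06,8.61,,1
Indole,,5.55e2,-5.06,7.80,,1
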