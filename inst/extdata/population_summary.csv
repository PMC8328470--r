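population,n_ind,ldh_native_pct,ldh_domestic_pct,mhc_dab_N,mhc_dab_R,mhc_dab_P,mhc_dab_Ho,mhc_dab_He,mhc_st_N,mhc_st_R,mhc_st_P,str_N,str_R,str_P,str_Ho,str_He
CAR,28,85.7,14.3,13,10.87,6,0.86,0.81,8,7.30,0,6.91,5.98,1.36,0.47,0.51
MEL,27,9.3,90.7,12,10.37,2,0.81,0.84,7,6.57,0,6.09,5.72,0.45,0.69,0.73
RAP,25,54.0,46.0,12,10.63,5,0.88,0.83,8,7.03,1,7.45,6.93,0.82,0.78,0.74
SCR,26,94.2,5.8,7,6.26,3,0.65,0.75,6,5.36,0,4.91,4.50,1.00,0.42,0.41
SIM,27,61.1,38.9,25,19.04,10,0.67,0.89,10,9.60,0,10.64,9.29,2.55,0.72,0.74
TRO,23,54.3,45.7,20,17.39,11,0.91,0.92,9,8.42,0,9.82,9.02,1.64,0.76,0.77
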