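condition,state,N,k_exp,k_theory,g_exp,g_theory,C1,C2
HD,NL,2664,1.67,1.67,0.0188,0.022,4.9e-4,4.40e-5
HD,diseased,2150,1.63,1.63,0.0186,0.0101,4.9e-4,2.20e-5
AD,NL,642,1.64,1.64,0.042,0.108,7.0e-4,2.30e-4
AD,diseased,1061,1.62,1.62,0.038,0.067,7.0e-4,1.90e-4
DS,NL,1916,1.52,1.52,0.017,0.017,5.0e-4,0.88e-4
DS,diseased,1365,1.47,1.47,0.010,0.010,5.0e-4,0.32e-4
PD,NL,19519,1.72,1.72,0.006,0.008,1.2e-3,7.00e-6
PD,diseased,8715,1.70,1.70,0.005,0.007,9.8e-4,7.00e-6
ALS,NL,103,1.75,1.75,0.369,0.359,4.8e-4,1.00e-4
ALS,diseased,72,1.69,1.69,0.222,0.225,1.0e-4,1.00e-4
Kidney,NL,5038,1.66,1.66,0.012,0.016,9.1e-4,4.00e-5
Kidney,diseased,5386,1.64,1.64,0.011,0.011,9.0e-4,0.25e-4
Diabetes,NL,3546,1.67,1.67,0.023,0.020,9.8e-4,4.50e-5
Diabetes,diseased,3504,1.65,1.65,0.010,0.013,9.8e-4,2.50e-5
OPA,NL,5263,1.69,1.69,0.0093,0.0081,9.0e-4,1.00e-5
OPA,diseased,7772,1.67,1.67,0.0055,0.0075,7.6e-4,1.00e-5
Ca,NL,3195,1.59,1.59,0.039,0.038,7.0e-4,1.46e-4
Ca,diseased,2576,1.57,1.58,0.032,0.032,7.0e-4,1.13e-4
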