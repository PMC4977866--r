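factor,bc_nsng,bc_rank_nsng,cc_nsng,cc_rank_nsng,bc_sng,bc_rank_sng,cc_sng,cc_rank_sng
Residence,0.221,1,0.600,1,0.127,3,0.704,1
Other drug use,0.176,2,0.581,2,0.209,1,0.704,1
Method of drug intake,0.174,3,0.581,2,0.007,14,0.528,12
Source of syringe,0.146,4,0.529,6,0.004,17,0.463,17
Age,0.130,5,0.514,8,0.066,5,0.655,4
Duration of drug injection,0.125,6,0.581,2,0.056,7,0.633,5
Drug use frequency,0.097,7,0.563,5,0.011,13,0.500,15
Ethnicity,0.070,8,0.500,9,0.121,4,0.613,6
Times reusing needle,0.041,9,0.439,14,0.037,9,0.613,6
Duration of drug abuse,0.029,10,0.529,6,0.017,11,0.594,8
Most recent drug use,0.028,11,0.486,10,0.013,12,0.576,10
Number of sexual partners,0.022,12,0.474,11,0.045,8,0.594,8
Education,0.008,13,0.375,16,0.000,18,0.404,19
STD diagnosis,0.005,14,0.462,12,0.000,18,0.432,18
HIV serostatus,0.003,15,0.450,13,0.066,5,0.679,3
Marital status,0.000,16,0.346,19,0.131,2,0.559,11
Occupation,NA,NA,NA,NA,0.031,10,0.514,13
Other infectious diseases,0.000,16,0.353,18,0.006,15,0.514,13
Drug of choice,0.000,16,0.375,16,0.006,15,0.475,16
Gender,0.000,16,0.409,14,0.000,18,0.365,20
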