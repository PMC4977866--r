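factor,category,reference,total,shared,uni_or,uni_lo,uni_hi,uni_p,factor_p,multi_or,multi_lo,multi_hi,multi_p,multi_factor_p
Residence,Baoshan,1,340,51,NA,NA,NA,NA,7.7e-25,NA,NA,NA,NA,1.9e-10
Residence,Zhaotong,0,381,157,4.0,2.8,5.7,6.9e-14,7.7e-25,3.6,2.4,5.7,3.8e-09,1.9e-10
Residence,Qujing,0,112,56,5.7,3.5,9.1,8.4e-13,7.7e-25,5.9,3.4,10.3,2.7e-10,1.9e-10
Residence,Dehong,0,140,74,6.4,4.1,9.9,4.3e-16,7.7e-25,3.0,1.7,5.2,1.2e-04,1.9e-10
Residence,Lincang,0,76,55,14.8,8.3,26.6,1.5e-19,7.7e-25,4.9,2.3,10.1,2.5e-05,1.9e-10
Gender,Male,1,1018,383,NA,NA,NA,NA,5.4e-01,NA,NA,NA,NA,NA
Gender,Female,0,31,10,0.8,0.4,1.7,5.4e-01,5.4e-01,NA,NA,NA,NA,NA
Age,13-25,1,200,71,NA,NA,NA,NA,3.5e-01,NA,NA,NA,NA,NA
Age,26-30,0,321,116,1.0,0.7,1.5,8.8e-01,3.5e-01,NA,NA,NA,NA,NA
Age,31-35,0,284,119,1.3,0.9,1.9,1.6e-01,3.5e-01,NA,NA,NA,NA,NA
Age,36-68,0,244,87,1.0,0.7,1.5,9.7e-01,3.5e-01,NA,NA,NA,NA,NA
Ethnicity,Han,1,852,301,NA,NA,NA,NA,3.1e-03,NA,NA,NA,NA,NA
Ethnicity,Minority,0,197,92,1.6,1.2,2.2,3.1e-03,3.1e-03,NA,NA,NA,NA,NA
Occupation,Various jobs,1,226,67,NA,NA,NA,NA,1.6e-02,NA,NA,NA,NA,NA
Occupation,Farmer,0,362,137,1.4,1.0,2.1,4.3e-02,1.6e-02,NA,NA,NA,NA,NA
Occupation,Jobless,0,461,189,1.6,1.2,2.3,4.0e-03,1.6e-02,NA,NA,NA,NA,NA
Marital status,Unmarried,1,485,197,NA,NA,NA,NA,2.3e-01,NA,NA,NA,NA,NA
Marital status,Married,0,387,131,0.7,0.6,1.0,4.1e-02,2.3e-01,NA,NA,NA,NA,NA
Marital status,Cohabitated,0,62,22,0.8,0.5,1.4,4.4e-01,2.3e-01,NA,NA,NA,NA,NA
Marital status,Divorced or widowed,0,115,43,0.9,0.6,1.3,5.3e-01,2.3e-01,NA,NA,NA,NA,NA
Education,None,1,67,38,NA,NA,NA,NA,8.9e-04,NA,NA,NA,NA,NA
Education,1-5 years,0,348,143,0.5,0.3,0.9,1.9e-02,8.9e-04,NA,NA,NA,NA,NA
Education,6-9 years,0,488,165,0.4,0.2,0.7,3.7e-04,8.9e-04,NA,NA,NA,NA,NA
Education,>10 years,0,146,47,0.4,0.2,0.7,8.3e-04,8.9e-04,NA,NA,NA,NA,NA
Drug of choice,Heroin,1,1010,377,NA,NA,NA,NA,6.4e-01,NA,NA,NA,NA,NA
Drug of choice,Heroin + others,0,39,16,1.2,0.6,2.2,6.4e-01,6.4e-01,NA,NA,NA,NA,NA
Other drug use,No,1,221,46,NA,NA,NA,NA,5.9e-12,NA,NA,NA,NA,2.1e-04
Other drug use,Diazepam,0,450,168,2.3,1.6,3.3,2.1e-05,5.9e-12,1.6,1.0,2.6,4.1e-02,2.1e-04
Other drug use,Diazepam + others,0,325,167,4.0,2.7,5.9,3.0e-12,5.9e-12,2.7,1.6,4.3,1.0e-04,2.1e-04
Other drug use,Other,0,53,12,1.1,0.5,2.3,7.7e-01,5.9e-12,0.9,0.4,2.2,8.0e-01,2.1e-04
Method of drug intake,Injection,1,496,169,NA,NA,NA,NA,3.2e-02,NA,NA,NA,NA,NA
Method of drug intake,Injection + oral,0,553,224,1.3,1.0,1.7,3.2e-02,3.2e-02,NA,NA,NA,NA,NA
Duration of drug abuse,<5 years,1,324,85,NA,NA,NA,NA,2.4e-07,NA,NA,NA,NA,NA
Duration of drug abuse,6-10 years,0,281,102,1.6,1.1,2.3,7.7e-03,2.4e-07,NA,NA,NA,NA,NA
Duration of drug abuse,11-15 years,0,281,124,2.2,1.6,3.1,4.7e-06,2.4e-07,NA,NA,NA,NA,NA
Duration of drug abuse,16-20 years,0,163,82,2.8,1.9,4.2,2.0e-07,2.4e-07,NA,NA,NA,NA,NA
Drug use frequency,<1,1,99,17,NA,NA,NA,NA,8.3e-05,NA,NA,NA,NA,NA
Drug use frequency,2,0,334,118,2.6,1.5,4.7,8.4e-04,8.3e-05,NA,NA,NA,NA,NA
Drug use frequency,3,0,390,164,3.5,2.0,6.1,1.1e-05,8.3e-05,NA,NA,NA,NA,NA
Drug use frequency,>4,0,226,94,3.4,1.9,6.2,3.6e-05,8.3e-05,NA,NA,NA,NA,NA
Most recent drug use,<1 year,1,624,225,NA,NA,NA,NA,3.0e-02,NA,NA,NA,NA,NA
Most recent drug use,1 year,0,336,123,1.0,0.8,1.3,8.7e-01,3.0e-02,NA,NA,NA,NA,NA
Most recent drug use,>2 years,0,89,45,1.8,1.2,2.8,9.0e-03,3.0e-02,NA,NA,NA,NA,NA
Duration of drug injection,<5 years,1,499,129,NA,NA,NA,NA,7.7e-13,NA,NA,NA,NA,5.3e-04
Duration of drug injection,6-10 years,0,464,216,2.5,1.9,3.3,3.5e-11,7.7e-13,1.7,1.2,2.4,1.2e-03,5.3e-04
Duration of drug injection,>11 years,0,86,48,3.6,2.3,5.8,8.2e-08,7.7e-13,2.6,1.4,4.8,2.0e-03,5.3e-04
Source of syringe,Clinic,1,145,26,NA,NA,NA,NA,8.8e-06,NA,NA,NA,NA,NA
Source of syringe,Hospital,0,123,51,3.2,1.9,5.7,3.3e-05,8.8e-06,NA,NA,NA,NA,NA
Source of syringe,Drugstore,0,692,276,3.0,1.9,4.8,1.4e-06,8.8e-06,NA,NA,NA,NA,NA
Source of syringe,Other,0,89,40,3.7,2.1,6.8,1.4e-05,8.8e-06,NA,NA,NA,NA,NA
Times reusing needle,1,1,638,164,NA,NA,NA,NA,1.6e-23,NA,NA,NA,NA,5.0e-14
Times reusing needle,2,0,277,134,2.7,2.0,3.6,3.6e-11,1.6e-23,2.3,1.6,3.2,3.3e-06,5.0e-14
Times reusing needle,>3,0,134,95,7.0,4.7,10.6,2.0e-20,1.6e-23,6.1,3.8,10.0,2.1e-13,5.0e-14
Number of sexual partners,None,1,121,45,NA,NA,NA,NA,2.1e-01,NA,NA,NA,NA,NA
Number of sexual partners,1,0,312,103,0.8,0.5,1.3,4.1e-01,2.1e-01,NA,NA,NA,NA,NA
Number of sexual partners,2-3,0,285,110,1.1,0.7,1.6,7.9e-01,2.1e-01,NA,NA,NA,NA,NA
Number of sexual partners,4-6,0,152,56,1.0,0.6,1.6,9.5e-01,2.1e-01,NA,NA,NA,NA,NA
Number of sexual partners,7-10,0,59,23,1.1,0.6,2.0,8.2e-01,2.1e-01,NA,NA,NA,NA,NA
Number of sexual partners,>11,0,120,56,1.5,0.9,2.5,1.4e-01,2.1e-01,NA,NA,NA,NA,NA
STD diagnosis,No,1,867,295,NA,NA,NA,NA,7.6e-07,NA,NA,NA,NA,NA
STD diagnosis,Yes,0,182,98,2.3,1.6,3.1,7.6e-07,7.6e-07,NA,NA,NA,NA,NA
HIV serostatus,Negative,1,853,254,NA,NA,NA,NA,9.9e-24,NA,NA,NA,NA,1.3e-06
HIV serostatus,Positive,0,196,139,5.8,4.1,8.1,9.9e-24,9.9e-24,3.1,2.0,4.9,1.3e-06,1.3e-06
Other infectious diseases,No,1,718,219,NA,NA,NA,NA,3.3e-12,NA,NA,NA,NA,1.3e-04
Other infectious diseases,Yes,0,160,97,3.5,2.5,5.0,4.1e-12,3.3e-12,2.5,1.6,3.8,2.6e-05,1.3e-04
Other infectious diseases,Unknown,0,171,77,1.9,1.3,2.6,3.3e-04,3.3e-12,1.3,0.9,2.0,1.8e-01,1.3e-04
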