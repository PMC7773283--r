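parameter,unit,group,timepoint,mean,sd
P_c,mm,cervical,PRE-2,13.39,2.06
P_c,mm,lumbar,PRE-2,14.06,1.64
P_c,mm,cervical,POST-1,13.31,2.10
P_c,mm,lumbar,POST-1,14.09,1.44
P_c,mm,cervical,POST-2,13.79,2.13
P_c,mm,lumbar,POST-2,14.65,1.20
P_d,mm,cervical,PRE-2,21.53,1.96
P_d,mm,lumbar,PRE-2,22.30,1.66
P_d,mm,cervical,POST-1,21.81,1.91
P_d,mm,lumbar,POST-1,22.30,1.47
P_d,mm,cervical,POST-2,22.05,1.97
P_d,mm,lumbar,POST-2,22.55,1.38
P_sas,mm,cervical,PRE-2,35.72,4.38
P_sas,mm,lumbar,PRE-2,37.46,3.91
P_sas,mm,cervical,POST-1,39.29,4.15
P_sas,mm,lumbar,POST-1,38.06,3.08
P_sas,mm,cervical,POST-2,40.60,4.82
P_sas,mm,lumbar,POST-2,39.02,2.88
A_c,mm^2,cervical,PRE-2,14.40,2.72
A_c,mm^2,lumbar,PRE-2,15.47,3.07
A_c,mm^2,cervical,POST-1,14.89,3.25
A_c,mm^2,lumbar,POST-1,16.12,2.57
A_c,mm^2,cervical,POST-2,15.46,3.46
A_c,mm^2,lumbar,POST-2,16.24,2.25
A_d,mm^2,cervical,PRE-2,38.21,6.22
A_d,mm^2,lumbar,PRE-2,40.10,5.89
A_d,mm^2,cervical,POST-1,38.89,6.00
A_d,mm^2,lumbar,POST-1,40.05,5.11
A_d,mm^2,cervical,POST-2,39.91,6.05
A_d,mm^2,lumbar,POST-2,40.72,4.88
A_sas,mm^2,cervical,PRE-2,23.81,4.66
A_sas,mm^2,lumbar,PRE-2,24.63,4.31
A_sas,mm^2,cervical,POST-1,22.51,4.50
A_sas,mm^2,lumbar,POST-1,23.76,3.76
A_sas,mm^2,cervical,POST-2,22.96,4.17
A_sas,mm^2,lumbar,POST-2,24.30,3.62
SA_c,cm^2,cervical,PRE-2,40.24,3.38
SA_c,cm^2,lumbar,PRE-2,42.40,2.71
SA_c,cm^2,cervical,POST-1,38.68,1.67
SA_c,cm^2,lumbar,POST-1,41.32,2.80
SA_c,cm^2,cervical,POST-2,39.85,3.43
SA_c,cm^2,lumbar,POST-2,42.97,1.76
SA_d,cm^2,cervical,PRE-2,64.85,3.83
SA_d,cm^2,lumbar,PRE-2,67.37,3.54
SA_d,cm^2,cervical,POST-1,63.59,4.72
SA_d,cm^2,lumbar,POST-1,65.55,3.03
SA_d,cm^2,cervical,POST-2,63.87,4.90
SA_d,cm^2,lumbar,POST-2,66.32,2.47
SA_sas,cm^2,cervical,PRE-2,105.09,7.17
SA_sas,cm^2,lumbar,PRE-2,109.78,6.07
SA_sas,cm^2,cervical,POST-1,102.27,6.12
SA_sas,cm^2,lumbar,POST-1,106.87,5.74
SA_sas,cm^2,cervical,POST-2,103.72,8.22
SA_sas,cm^2,lumbar,POST-2,109.29,4.22
V_c,mL,cervical,PRE-2,4.33,0.39
V_c,mL,lumbar,PRE-2,4.70,0.59
V_c,mL,cervical,POST-1,4.35,0.41
V_c,mL,lumbar,POST-1,4.76,0.44
V_c,mL,cervical,POST-2,4.48,0.39
V_c,mL,lumbar,POST-2,4.80,0.32
V_d,mL,cervical,PRE-2,11.51,1.18
V_d,mL,lumbar,PRE-2,12.13,1.21
V_d,mL,cervical,POST-1,11.35,1.10
V_d,mL,lumbar,POST-1,11.80,0.95
V_d,mL,cervical,POST-2,11.59,1.03
V_d,mL,lumbar,POST-2,12.00,0.87
V_sas,mL,cervical,PRE-2,7.17,0.82
V_sas,mL,lumbar,PRE-2,7.43,0.79
V_sas,mL,cervical,POST-1,6.57,0.77
V_sas,mL,lumbar,POST-1,6.99,0.57
V_sas,mL,cervical,POST-2,6.68,0.67
V_sas,mL,lumbar,POST-2,7.15,0.58
D_h,mm,cervical,PRE-2,2.67,0.34
D_h,mm,lumbar,PRE-2,2.66,0.37
D_h,mm,cervical,POST-1,2.35,0.43
D_h,mm,lumbar,POST-1,2.54,0.34
D_h,mm,cervical,POST-2,2.31,0.29
D_h,mm,lumbar,POST-2,2.52,0.29
Re,-,cervical,PRE-2,32.32,14.12
Re,-,lumbar,PRE-2,28.51,13.12
Re,-,cervical,POST-1,15.13,11.74
Re,-,lumbar,POST-1,21.77,11.61
Re,-,cervical,POST-2,10.79,6.58
Re,-,lumbar,POST-2,21.45,13.03
alpha,-,cervical,PRE-2,5.45,0.86
alpha,-,lumbar,PRE-2,5.43,0.65
alpha,-,cervical,POST-1,4.61,1.04
alpha,-,lumbar,POST-1,5.05,0.66
alpha,-,cervical,POST-2,4.42,0.56
alpha,-,lumbar,POST-2,5.09,0.59
U_peak_sys,cm/s,cervical,PRE-2,-0.92,0.42
U_peak_sys,cm/s,lumbar,PRE-2,-0.84,0.36
U_peak_sys,cm/s,cervical,POST-1,-0.49,0.40
U_peak_sys,cm/s,lumbar,POST-1,-0.63,0.32
U_peak_sys,cm/s,cervical,POST-2,-0.34,0.21
U_peak_sys,cm/s,lumbar,POST-2,-0.64,0.39
U_peak_dia,cm/s,cervical,PRE-2,0.66,0.30
U_peak_dia,cm/s,lumbar,PRE-2,0.56,0.23
U_peak_dia,cm/s,cervical,POST-1,0.40,0.29
U_peak_dia,cm/s,lumbar,POST-1,0.46,0.23
U_peak_dia,cm/s,cervical,POST-2,0.32,0.19
U_peak_dia,cm/s,lumbar,POST-2,0.49,0.26
Q_peak_sys,mL/s,cervical,PRE-2,-0.21,0.09
Q_peak_sys,mL/s,lumbar,PRE-2,-0.19,0.08
Q_peak_sys,mL/s,cervical,POST-1,-0.11,0.08
Q_peak_sys,mL/s,lumbar,POST-1,-0.15,0.08
Q_peak_sys,mL/s,cervical,POST-2,-0.08,0.04
Q_peak_sys,mL/s,lumbar,POST-2,-0.15,0.09
Q_peak_dia,mL/s,cervical,PRE-2,0.15,0.06
Q_peak_dia,mL/s,lumbar,PRE-2,0.13,0.05
Q_peak_dia,mL/s,cervical,POST-1,0.08,0.05
Q_peak_dia,mL/s,lumbar,POST-1,0.11,0.05
Q_peak_dia,mL/s,cervical,POST-2,0.07,0.04
Q_peak_dia,mL/s,lumbar,POST-2,0.11,0.06
Q_a,mL/s,cervical,PRE-2,0.36,0.22
Q_a,mL/s,lumbar,PRE-2,0.32,0.25
Q_a,mL/s,cervical,POST-1,0.19,0.11
Q_a,mL/s,lumbar,POST-1,0.25,0.20
Q_a,mL/s,cervical,POST-2,0.15,0.08
Q_a,mL/s,lumbar,POST-2,0.26,0.21
SV,mL,cervical,PRE-2,0.06,0.02
SV,mL,lumbar,PRE-2,0.05,0.03
SV,mL,cervical,POST-1,0.03,0.02
SV,mL,lumbar,POST-1,0.05,0.03
SV,mL,cervical,POST-2,0.03,0.01
SV,mL,lumbar,POST-2,0.04,0.03
PWV,m/s,cervical,PRE-2,1.15,1.21
PWV,m/s,lumbar,PRE-2,1.11,0.21
PWV,m/s,cervical,POST-1,1.25,0.59
PWV,m/s,lumbar,POST-1,1.16,0.52
PWV,m/s,cervical,POST-2,1.16,0.06
PWV,m/s,lumbar,POST-2,1.09,0.21
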