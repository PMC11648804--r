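genotype,trait,system,season,LER
H1,CWH,IC1,1,1.25
H1,CWH,IC1,2,1.37
H1,CWH,IC2,1,0.96
H1,CWH,IC2,2,0.94
H1,GY,IC1,1,1.08
H1,GY,IC1,2,1.41
H1,GY,IC2,1,0.63
H1,GY,IC2,2,0.79
H2,CWH,IC1,1,1.33
H2,CWH,IC1,2,1.34
H2,CWH,IC2,1,0.88
H2,CWH,IC2,2,0.78
H2,GY,IC1,1,1.28
H2,GY,IC1,2,1.3
H2,GY,IC2,1,0.75
H2,GY,IC2,2,0.82
H3,CWH,IC1,1,1.22
H3,CWH,IC1,2,1.43
H3,CWH,IC2,1,0.73
H3,CWH,IC2,2,1.17
H3,GY,IC1,1,1.16
H3,GY,IC1,2,1.23
H3,GY,IC2,1,0.52
H3,GY,IC2,2,1.02
H4,CWH,IC1,1,1.31
H4,CWH,IC1,2,1.11
H4,CWH,IC2,1,0.92
H4,CWH,IC2,2,0.84
H4,GY,IC1,1,1.37
H4,GY,IC1,2,1.08
H4,GY,IC2,1,0.73
H4,GY,IC2,2,0.96
H5,CWH,IC1,1,1.36
H5,CWH,IC1,2,1.25
H5,CWH,IC2,1,0.78
H5,CWH,IC2,2,0.72
H5,GY,IC1,1,1.57
H5,GY,IC1,2,1.15
H5,GY,IC2,1,0.73
H5,GY,IC2,2,0.75
H6,CWH,IC1,1,1.34
H6,CWH,IC1,2,1.3
H6,CWH,IC2,1,0.9
H6,CWH,IC2,2,0.75
H6,GY,IC1,1,1.42
H6,GY,IC1,2,1.27
H6,GY,IC2,1,0.56
H6,GY,IC2,2,0.72
H7,CWH,IC1,1,1.39
H7,CWH,IC1,2,1.27
H7,CWH,IC2,1,1.05
H7,CWH,IC2,2,0.93
H7,GY,IC1,1,1.37
H7,GY,IC1,2,1.19
H7,GY,IC2,1,1.01
H7,GY,IC2,2,0.84
H8,CWH,IC1,1,1.32
H8,CWH,IC1,2,1.44
H8,CWH,IC2,1,0.7
H8,CWH,IC2,2,1.07
H8,GY,IC1,1,1.32
H8,GY,IC1,2,1.37
H8,GY,IC2,1,0.65
H8,GY,IC2,2,0.9
H9,CWH,IC1,1,1.48
H9,CWH,IC1,2,1.42
H9,CWH,IC2,1,0.84
H9,CWH,IC2,2,0.95
H9,GY,IC1,1,1.36
H9,GY,IC1,2,1.5
H9,GY,IC2,1,1.03
H9,GY,IC2,2,1.11
H10,CWH,IC1,1,1.44
H10,CWH,IC1,2,1.17
H10,CWH,IC2,1,0.8
H10,CWH,IC2,2,0.84
H10,GY,IC1,1,1.32
H10,GY,IC1,2,1.61
H10,GY,IC2,1,0.68
H10,GY,IC2,2,1.16
H11,CWH,IC1,1,1.07
H11,CWH,IC1,2,1.03
H11,CWH,IC2,1,0.64
H11,CWH,IC2,2,0.84
H11,GY,IC1,1,1.24
H11,GY,IC1,2,1.01
H11,GY,IC2,1,0.74
H11,GY,IC2,2,0.81
H12,CWH,IC1,1,1.28
H12,CWH,IC1,2,1.14
H12,CWH,IC2,1,0.67
H12,CWH,IC2,2,0.79
H12,GY,IC1,1,1.3
H12,GY,IC1,2,1.55
H12,GY,IC2,1,0.6
H12,GY,IC2,2,1.01
H13,CWH,IC1,1,1.29
H13,CWH,IC1,2,1.43
H13,CWH,IC2,1,0.81
H13,CWH,IC2,2,0.96
H13,GY,IC1,1,1.32
H13,GY,IC1,2,1.43
H13,GY,IC2,1,0.86
H13,GY,IC2,2,0.75
H14,CWH,IC1,1,1.51
H14,CWH,IC1,2,1.2
H14,CWH,IC2,1,0.83
H14,CWH,IC2,2,0.84
H14,GY,IC1,1,1.4
H14,GY,IC1,2,1.15
H14,GY,IC2,1,0.76
H14,GY,IC2,2,0.91
H15,CWH,IC1,1,1.34
H15,CWH,IC1,2,0.85
H15,CWH,IC2,1,0.81
H15,CWH,IC2,2,0.76
H15,GY,IC1,1,1.4
H15,GY,IC1,2,1.06
H15,GY,IC2,1,0.78
H15,GY,IC2,2,0.68
H16,CWH,IC1,1,1.39
H16,CWH,IC1,2,0.92
H16,CWH,IC2,1,0.89
H16,CWH,IC2,2,0.63
H16,GY,IC1,1,1.38
H16,GY,IC1,2,1.06
H16,GY,IC2,1,0.77
H16,GY,IC2,2,0.68
H17,CWH,IC1,1,1.2
H17,CWH,IC1,2,1.05
H17,CWH,IC2,1,0.86
H17,CWH,IC2,2,0.75
H17,GY,IC1,1,1.34
H17,GY,IC1,2,0.9
H17,GY,IC2,1,0.72
H17,GY,IC2,2,0.64
H18,CWH,IC1,1,1.25
H18,CWH,IC1,2,1.52
H18,CWH,IC2,1,0.98
H18,CWH,IC2,2,1.06
H18,GY,IC1,1,1.29
H18,GY,IC1,2,1.52
H18,GY,IC2,1,0.91
H18,GY,IC2,2,1.22
H19,CWH,IC1,1,1.25
H19,CWH,IC1,2,1.39
H19,CWH,IC2,1,0.72
H19,CWH,IC2,2,0.8
H19,GY,IC1,1,1.29
H19,GY,IC1,2,1.46
H19,GY,IC2,1,0.8
H19,GY,IC2,2,0.89
H20,CWH,IC1,1,1.34
H20,CWH,IC1,2,1.16
H20,CWH,IC2,1,1.05
H20,CWH,IC2,2,0.74
H20,GY,IC1,1,1.36
H20,GY,IC1,2,1.07
H20,GY,IC2,1,0.87
H20,GY,IC2,2,0.81
T1,CWH,IC1,1,1.98
T1,CWH,IC1,2,1.21
T1,CWH,IC2,1,1.23
T1,CWH,IC2,2,0.65
T1,GY,IC1,1,1.66
T1,GY,IC1,2,0.96
T1,GY,IC2,1,0.88
T1,GY,IC2,2,0.57
T2,CWH,IC1,1,1.33
T2,CWH,IC1,2,1.31
T2,CWH,IC2,1,0.72
T2,CWH,IC2,2,0.93
T2,GY,IC1,1,1.23
T2,GY,IC1,2,1.27
T2,GY,IC2,1,0.5
T2,GY,IC2,2,1.08
T3,CWH,IC1,1,1.54
T3,CWH,IC1,2,1.65
T3,CWH,IC2,1,1.01
T3,CWH,IC2,2,0.88
T3,GY,IC1,1,1.32
T3,GY,IC1,2,1.53
T3,GY,IC2,1,0.68
T3,GY,IC2,2,0.7
T4,CWH,IC1,1,1.22
T4,CWH,IC1,2,1.12
T4,CWH,IC2,1,0.64
T4,CWH,IC2,2,1.05
T4,GY,IC1,1,1.16
T4,GY,IC1,2,1.19
T4,GY,IC2,1,0.87
T4,GY,IC2,2,1.23
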