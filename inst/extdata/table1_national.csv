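age_group,year,sex,index,estimate,lower,upper
1-4,1990,both,dmft,2.22,0.27,4.44
1-4,1990,female,dmft,1.99,0.13,4.2
1-4,1990,male,dmft,2.45,0.41,4.67
1-4,1990,both,dt,1.98,0.09,4.38
1-4,1990,female,dt,1.76,0.01,4.16
1-4,1990,male,dt,2.19,0.16,4.59
1-4,1990,both,mt,0.01,0,0.36
1-4,1990,female,mt,0,0,0.32
1-4,1990,male,mt,0.02,0,0.4
1-4,1990,both,ft,0.23,0.03,0.61
1-4,1990,female,ft,0.23,0.03,0.61
1-4,1990,male,ft,0.23,0.04,0.61
1-4,2000,both,dmft,2.65,0.52,4.94
1-4,2000,female,dmft,2.45,0.35,4.74
1-4,2000,male,dmft,2.84,0.67,5.13
1-4,2000,both,dt,2.36,0.08,5.37
1-4,2000,female,dt,2.16,0.01,5.25
1-4,2000,male,dt,2.54,0.15,5.49
1-4,2000,both,mt,0,0,0.37
1-4,2000,female,mt,0,0,0.34
1-4,2000,male,mt,0.01,0,0.4
1-4,2000,both,ft,0.29,0.05,0.77
1-4,2000,female,ft,0.29,0.05,0.78
1-4,2000,male,ft,0.29,0.05,0.76
1-4,2010,both,dmft,2.88,0.71,5.18
1-4,2010,female,dmft,2.74,0.58,5.04
1-4,2010,male,dmft,3.01,0.84,5.32
1-4,2010,both,dt,2.56,0.18,5.36
1-4,2010,female,dt,2.43,0.1,5.27
1-4,2010,male,dt,2.7,0.26,5.45
1-4,2010,both,mt,0,0,0.34
1-4,2010,female,mt,0,0,0.32
1-4,2010,male,mt,0,0,0.36
1-4,2010,both,ft,0.31,0.07,0.76
1-4,2010,female,ft,0.32,0.07,0.77
1-4,2010,male,ft,0.31,0.07,0.75
1-4,2017,both,dmft,3.01,0.92,5.18
1-4,2017,female,dmft,2.91,0.82,5.08
1-4,2017,male,dmft,3.1,1.01,5.27
1-4,2017,both,dt,2.7,0.4,5.11
1-4,2017,female,dt,2.61,0.32,5.03
1-4,2017,male,dt,2.79,0.47,5.19
1-4,2017,both,mt,0,0,0.31
1-4,2017,female,mt,0,0,0.3
1-4,2017,male,mt,0,0,0.32
1-4,2017,both,ft,0.3,0.07,0.69
1-4,2017,female,ft,0.3,0.07,0.69
1-4,2017,male,ft,0.3,0.07,0.68
5-9,1990,both,dmft,4.34,2.17,6.57
5-9,1990,female,dmft,4.13,1.96,6.34
5-9,1990,male,dmft,4.55,2.37,6.78
5-9,1990,both,dt,3.64,1.45,5.85
5-9,1990,female,dt,3.48,1.27,5.7
5-9,1990,male,dt,3.8,1.62,5.99
5-9,1990,both,mt,0.38,0.03,0.8
5-9,1990,female,mt,0.33,0,0.76
5-9,1990,male,mt,0.42,0.05,0.85
5-9,1990,both,ft,0.32,0.08,0.67
5-9,1990,female,ft,0.33,0.07,0.67
5-9,1990,male,ft,0.32,0.08,0.67
5-9,2000,both,dmft,4.78,2.55,7.06
5-9,2000,female,dmft,4.62,2.4,6.9
5-9,2000,male,dmft,4.92,2.7,7.21
5-9,2000,both,dt,4.05,1.62,6.47
5-9,2000,female,dt,3.92,1.48,6.37
5-9,2000,male,dt,4.16,1.76,6.57
5-9,2000,both,mt,0.38,0.02,0.85
5-9,2000,female,mt,0.34,0,0.82
5-9,2000,male,mt,0.41,0.03,0.88
5-9,2000,both,ft,0.35,0.09,0.74
5-9,2000,female,ft,0.36,0.09,0.74
5-9,2000,male,ft,0.35,0.1,0.73
5-9,2010,both,dmft,4.97,2.78,7.24
5-9,2010,female,dmft,4.89,2.7,7.15
5-9,2010,male,dmft,5.05,2.85,7.32
5-9,2010,both,dt,4.22,1.88,6.55
5-9,2010,female,dt,4.16,1.81,6.49
5-9,2010,male,dt,4.29,1.94,6.61
5-9,2010,both,mt,0.38,0.02,0.83
5-9,2010,female,mt,0.36,0,0.81
5-9,2010,male,mt,0.4,0.03,0.85
5-9,2010,both,ft,0.37,0.11,0.74
5-9,2010,female,ft,0.37,0.1,0.74
5-9,2010,male,ft,0.36,0.11,0.73
5-9,2017,both,dmft,5.06,2.99,7.2
5-9,2017,female,dmft,5.04,2.97,7.17
5-9,2017,male,dmft,5.08,3.01,7.22
5-9,2017,both,dt,4.34,2.17,6.48
5-9,2017,female,dt,4.32,2.15,6.46
5-9,2017,male,dt,4.36,2.19,6.49
5-9,2017,both,mt,0.37,0.02,0.79
5-9,2017,female,mt,0.36,0,0.78
5-9,2017,male,mt,0.38,0.03,0.8
5-9,2017,both,ft,0.35,0.11,0.7
5-9,2017,female,ft,0.36,0.11,0.7
5-9,2017,male,ft,0.35,0.11,0.69
10-14,1990,both,dmft,6.42,4.15,8.75
10-14,1990,female,dmft,6.23,3.98,8.54
10-14,1990,male,dmft,6.6,4.32,8.94
10-14,1990,both,dt,5.2,3.01,7.33
10-14,1990,female,dt,5.05,2.87,7.17
10-14,1990,male,dt,5.33,3.13,7.48
10-14,1990,both,mt,0.9,0.48,1.32
10-14,1990,female,mt,0.86,0.4,1.27
10-14,1990,male,mt,0.95,0.52,1.37
10-14,1990,both,ft,0.32,0.06,0.67
10-14,1990,female,ft,0.33,0.06,0.67
10-14,1990,male,ft,0.32,0.07,0.66
10-14,2000,both,dmft,6.83,4.41,9.3
10-14,2000,female,dmft,6.73,4.3,9.18
10-14,2000,male,dmft,6.93,4.51,9.41
10-14,2000,both,dt,5.55,3.11,7.92
10-14,2000,female,dt,5.46,3.01,7.84
10-14,2000,male,dt,5.63,3.21,7.98
10-14,2000,both,mt,0.95,0.48,1.42
10-14,2000,female,mt,0.93,0.5,1.4
10-14,2000,male,mt,0.98,0.51,1.45
10-14,2000,both,ft,0.33,0.06,0.71
10-14,2000,female,ft,0.34,0.06,0.72
10-14,2000,male,ft,0.32,0.07,0.7
10-14,2010,both,dmft,7.01,4.5,9.56
10-14,2010,female,dmft,7,4.48,9.56
10-14,2010,male,dmft,7.02,4.52,9.56
10-14,2010,both,dt,5.71,3.2,8.14
10-14,2010,female,dt,5.7,3.16,8.16
10-14,2010,male,dt,5.72,3.25,8.12
10-14,2010,both,mt,0.96,0.47,1.44
10-14,2010,female,mt,0.95,0.5,1.43
10-14,2010,male,mt,0.96,0.49,1.44
10-14,2010,both,ft,0.34,0.07,0.73
10-14,2010,female,ft,0.35,0.07,0.75
10-14,2010,male,ft,0.33,0.07,0.72
10-14,2017,both,dmft,7.06,4.57,9.56
10-14,2017,female,dmft,7.12,4.63,9.65
10-14,2017,male,dmft,6.99,4.51,9.48
10-14,2017,both,dt,5.79,3.32,8.18
10-14,2017,female,dt,5.84,3.31,8.28
10-14,2017,male,dt,5.75,3.32,8.09
10-14,2017,both,mt,0.92,0.45,1.39
10-14,2017,female,mt,0.93,0.4,1.4
10-14,2017,male,mt,0.92,0.45,1.38
10-14,2017,both,ft,0.34,0.07,0.73
10-14,2017,female,ft,0.35,0.08,0.75
10-14,2017,male,ft,0.33,0.07,0.71
all,1990,both,dmft,4.37,2.23,6.62
all,1990,female,dmft,4.15,2.04,6.39
all,1990,male,dmft,4.58,2.41,6.84
all,1990,both,dt,3.64,1.53,5.88
all,1990,female,dt,3.45,1.39,5.7
all,1990,male,dt,3.81,1.67,6.05
all,1990,both,mt,0.44,0.17,0.84
all,1990,female,mt,0.4,0.1,0.79
all,1990,male,mt,0.47,0.19,0.88
all,1990,both,ft,0.3,0.06,0.65
all,1990,female,ft,0.3,0.05,0.65
all,1990,male,ft,0.29,0.07,0.65
all,2000,both,dmft,5.09,2.81,7.45
all,2000,female,dmft,4.95,2.68,7.31
all,2000,male,dmft,5.23,2.94,7.59
all,2000,both,dt,4.25,1.85,6.79
all,2000,female,dt,4.12,1.75,6.7
all,2000,male,dt,4.36,1.95,6.88
all,2000,both,mt,0.52,0.2,0.97
all,2000,female,mt,0.5,0.2,0.94
all,2000,male,mt,0.54,0.22,0.99
all,2000,both,ft,0.33,0.07,0.73
all,2000,female,ft,0.33,0.07,0.75
all,2000,male,ft,0.32,0.07,0.72
all,2010,both,dmft,5.08,2.78,7.46
all,2010,female,dmft,5.01,2.71,7.39
all,2010,male,dmft,5.15,2.85,7.52
all,2010,both,dt,4.26,1.85,6.77
all,2010,female,dt,4.2,1.79,6.73
all,2010,male,dt,4.33,1.91,6.8
all,2010,both,mt,0.47,0.18,0.9
all,2010,female,mt,0.46,0.2,0.89
all,2010,male,mt,0.48,0.18,0.92
all,2010,both,ft,0.34,0.08,0.74
all,2010,female,ft,0.35,0.08,0.75
all,2010,male,ft,0.34,0.08,0.73
all,2017,both,dmft,5.03,2.82,7.29
all,2017,female,dmft,5.01,2.8,7.28
all,2017,male,dmft,5.04,2.83,7.3
all,2017,both,dt,4.27,1.96,6.57
all,2017,female,dt,4.25,1.93,6.57
all,2017,male,dt,4.28,1.99,6.57
all,2017,both,mt,0.43,0.15,0.82
all,2017,female,mt,0.42,0.1,0.82
all,2017,male,mt,0.43,0.15,0.83
all,2017,both,ft,0.33,0.09,0.7
all,2017,female,ft,0.34,0.09,0.71
all,2017,male,ft,0.33,0.08,0.69
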