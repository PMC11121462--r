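"table","parameter","group","n","mean","sd","ci_low","ci_high"
"t1","Glu","Acacia",213,27.4,3.87,26.88,27.93
"t1","Glu","Honeydew",29,29.33,5.17,27.37,31.3
"t1","Glu","Linden",34,29.2,3.91,27.83,30.56
"t1","Glu","Monofloral",8,31.67,7.53,25.37,37.96
"t1","Glu","Polyfloral",302,31.39,4.6,30.87,31.91
"t1","Glu","Sunflower",23,34.57,3.98,32.85,36.29
"t1","Fru","Acacia",213,40.83,5.83,40.04,41.62
"t1","Fru","Honeydew",29,37.84,6.32,35.44,40.25
"t1","Fru","Linden",34,35.39,5.82,33.36,37.42
"t1","Fru","Monofloral",8,35.41,5.17,31.09,39.73
"t1","Fru","Polyfloral",302,38.68,5.2,38.09,39.26
"t1","Fru","Sunflower",23,37.83,3.26,36.42,39.24
"t1","Suc","Acacia",213,1.19,1.79,0.94,1.43
"t1","Suc","Honeydew",29,0.46,0.61,0.23,0.69
"t1","Suc","Linden",34,0.64,1.08,0.27,1.02
"t1","Suc","Polyfloral",302,0.63,1.41,0.47,0.79
"t1","Suc","Sunflower",23,0.34,0.23,0.24,0.44
"t1","5-HMF","Acacia",213,5.71,8.2,4.6,6.82
"t1","5-HMF","Honeydew",29,6.34,12.66,1.52,11.15
"t1","5-HMF","Linden",34,5.41,6.37,3.18,7.63
"t1","5-HMF","Monofloral",8,11.84,19.74,-4.66,28.34
"t1","5-HMF","Polyfloral",302,8.31,12.36,6.91,9.71
"t1","5-HMF","Sunflower",23,4.85,8.34,1.25,8.46
"t1","MC","Acacia",213,16.19,1.07,16.04,16.33
"t1","MC","Honeydew",29,16.36,2.1,15.56,17.15
"t1","MC","Linden",34,16.61,1.1,16.23,17
"t1","MC","Monofloral",8,17.2,2.04,15.49,18.91
"t1","MC","Polyfloral",302,16.45,1.13,16.33,16.58
"t1","MC","Sunflower",23,17.51,1.37,16.92,18.11
"t1","Acid","Acacia",213,11.44,5.05,10.76,12.12
"t1","Acid","Honeydew",29,30.17,8.07,27.1,33.24
"t1","Acid","Linden",34,16.33,6.9,13.92,18.74
"t1","Acid","Monofloral",8,15.08,8.16,8.25,21.9
"t1","Acid","Polyfloral",302,21.04,9.33,19.98,22.09
"t1","Acid","Sunflower",23,23,7.22,19.88,26.12
"t1","Dia","Acacia",213,13.06,7.64,12.03,14.09
"t1","Dia","Honeydew",29,12.8,3.14,11.6,13.99
"t1","Dia","Linden",34,12.9,2.36,12.08,13.72
"t1","Dia","Monofloral",8,11.9,2.87,9.5,14.3
"t1","Dia","Polyfloral",302,12.9,3.43,12.51,13.29
"t1","Dia","Sunflower",23,13.45,2.5,12.37,14.53
"t1","Ins","Acacia",213,0.01,0.01,0.01,0.01
"t1","Ins","Honeydew",29,0.01,0,0.01,0.01
"t1","Ins","Linden",34,0.01,0,0.01,0.01
"t1","Ins","Monofloral",8,0.01,0,0.01,0.01
"t1","Ins","Polyfloral",302,0.01,0.01,0.01,0.01
"t1","Ins","Sunflower",23,0.01,0.01,0.01,0.02
"t1","Econd","Acacia",213,0.2,0.1,0.18,0.21
"t1","Econd","Honeydew",29,1.14,0.27,1.03,1.24
"t1","Econd","Linden",34,0.48,0.19,0.42,0.54
"t1","Econd","Monofloral",8,0.25,0.16,0.12,0.38
"t1","Econd","Polyfloral",302,0.4,0.15,0.38,0.42
"t1","Econd","Sunflower",23,0.39,0.09,0.36,0.43
"t2","Glu","2018",209,28.84,4.89,28.17,29.51
"t2","Glu","2019",80,31.51,4.44,30.52,32.49
"t2","Glu","2020",78,28.86,4.23,27.91,29.82
"t2","Glu","2021",108,30.97,4.87,30.04,31.9
"t2","Glu","2022",113,30.29,4.79,29.4,31.19
"t2","Glu","2023",21,30.53,4.39,28.53,32.52
"t2","Fru","2018",209,37.13,6.02,36.31,37.95
"t2","Fru","2019",80,39.73,4.58,38.71,40.75
"t2","Fru","2020",78,40.95,5.15,39.79,42.11
"t2","Fru","2021",108,39.76,5.53,38.7,40.81
"t2","Fru","2022",113,39.97,5.38,38.97,40.98
"t2","Fru","2023",21,42.25,2.52,41.1,43.39
"t2","Suc","2018",209,0.78,1.67,0.55,1.01
"t2","Suc","2019",80,0.66,0.69,0.51,0.81
"t2","Suc","2020",78,0.96,1.96,0.52,1.4
"t2","Suc","2021",108,0.8,1.65,0.48,1.11
"t2","Suc","2022",113,0.68,0.9,0.51,0.85
"t2","Suc","2023",21,1.59,1.9,0.73,2.45
"t2","5-HMF","2018",209,9.92,12.71,8.19,11.65
"t2","5-HMF","2019",80,8.94,14.61,5.69,12.19
"t2","5-HMF","2020",78,3.96,4.28,3,4.93
"t2","5-HMF","2021",108,4.56,7.95,3.05,6.08
"t2","5-HMF","2022",113,5.44,8.62,3.83,7.04
"t2","5-HMF","2023",21,4.49,6.39,1.58,7.4
"t2","MC","2018",209,16.34,1.28,16.17,16.52
"t2","MC","2019",80,16.29,0.98,16.07,16.5
"t2","MC","2020",78,16.46,1.35,16.16,16.76
"t2","MC","2021",108,16.52,1.22,16.29,16.76
"t2","MC","2022",113,16.49,1.08,16.29,16.69
"t2","MC","2023",21,16.5,1.7,15.73,17.28
"t2","Acid","2018",209,17.18,8.71,15.99,18.36
"t2","Acid","2019",80,20.21,9.72,18.04,22.37
"t2","Acid","2020",78,17.36,9.87,15.13,19.59
"t2","Acid","2021",108,19.34,7.61,17.89,20.79
"t2","Acid","2022",113,15.65,7.84,14.19,17.11
"t2","Acid","2023",21,21.53,20.14,12.36,30.7
"t2","Dia","2018",209,13.53,7.99,12.44,14.62
"t2","Dia","2019",80,13.73,3.11,13.04,14.42
"t2","Dia","2020",78,13.99,1.84,13.58,14.41
"t2","Dia","2021",108,12.02,2.39,11.57,12.48
"t2","Dia","2022",113,11.91,3.17,11.32,12.5
"t2","Dia","2023",21,10.98,1.61,10.25,11.72
"t2","Ins","2018",209,0.01,0,0.01,0.01
"t2","Ins","2019",80,0.01,0,0.01,0.01
"t2","Ins","2020",78,0.01,0,0.01,0.01
"t2","Ins","2021",108,0.01,0,0.01,0.01
"t2","Ins","2022",113,0.01,0.01,0.01,0.02
"t2","Ins","2023",21,0.02,0.01,0.01,0.02
"t2","Econd","2018",209,0.37,0.24,0.34,0.4
"t2","Econd","2019",80,0.46,0.35,0.38,0.54
"t2","Econd","2020",78,0.31,0.14,0.27,0.34
"t2","Econd","2021",108,0.39,0.25,0.34,0.43
"t2","Econd","2022",113,0.33,0.2,0.29,0.37
"t2","Econd","2023",21,0.31,0.16,0.24,0.38
"t3","Glu","Western region",114,29.59,5.34,28.6,30.58
"t3","Glu","Belgrade",205,30.3,4.73,29.65,30.95
"t3","Glu","Northern region",149,30.02,4.99,29.21,30.83
"t3","Glu","Central region",29,27.84,4.03,26.3,29.37
"t3","Glu","Eastern region",92,29.72,4.17,28.85,30.58
"t3","Glu","Southern region",20,30.56,4.55,28.43,32.69
"t3","Fru","Western region",114,38.93,5.42,37.93,39.94
"t3","Fru","Belgrade",205,39.46,5.43,38.71,40.21
"t3","Fru","Northern region",149,38.49,6.26,37.48,39.51
"t3","Fru","Central region",29,38.34,7.2,35.6,41.08
"t3","Fru","Eastern region",92,39.86,4.25,38.98,40.74
"t3","Fru","Southern region",20,39.41,7.12,36.07,42.74
"t3","Suc","Western region",114,1.16,2.16,0.76,1.57
"t3","Suc","Belgrade",205,0.75,1.35,0.56,0.93
"t3","Suc","Northern region",149,0.62,0.97,0.47,0.78
"t3","Suc","Central region",29,0.58,0.71,0.31,0.85
"t3","Suc","Eastern region",92,0.85,1.82,0.47,1.23
"t3","Suc","Southern region",20,0.63,0.62,0.34,0.92
"t3","5-HMF","Western region",114,5.62,8.55,4.04,7.21
"t3","5-HMF","Belgrade",205,8.01,12.32,6.32,9.71
"t3","5-HMF","Northern region",149,7.06,10.44,5.37,8.75
"t3","5-HMF","Central region",29,6,8.53,2.76,9.25
"t3","5-HMF","Eastern region",92,7.85,12.02,5.36,10.34
"t3","5-HMF","Southern region",20,3.35,3.8,1.58,5.13
"t3","MC","Western region",114,16.41,1.15,16.2,16.62
"t3","MC","Belgrade",205,16.31,1.17,16.15,16.47
"t3","MC","Northern region",149,16.71,1.19,16.52,16.9
"t3","MC","Central region",29,16.31,0.94,15.95,16.67
"t3","MC","Eastern region",92,16.31,1.51,15.99,16.62
"t3","MC","Southern region",20,16,0.97,15.55,16.45
"t3","Acid","Western region",114,18.11,8.89,16.46,19.76
"t3","Acid","Belgrade",205,17.72,9.12,16.46,18.97
"t3","Acid","Northern region",149,17.96,8.41,16.6,19.32
"t3","Acid","Central region",29,15.87,8.15,12.77,18.97
"t3","Acid","Eastern region",92,18.25,12.46,15.66,20.83
"t3","Acid","Southern region",20,17.89,7.54,14.36,21.41
"t3","Dia","Western region",114,13.23,3.72,12.54,13.92
"t3","Dia","Belgrade",205,13.28,7.7,12.22,14.34
"t3","Dia","Northern region",149,12.94,3.37,12.39,13.48
"t3","Dia","Central region",29,12.33,2.92,11.22,13.44
"t3","Dia","Eastern region",92,12.15,2.86,11.55,12.74
"t3","Dia","Southern region",20,12.98,2.9,11.62,14.34
"t3","Ins","Western region",114,0.01,0.01,0.01,0.01
"t3","Ins","Belgrade",205,0.01,0,0.01,0.01
"t3","Ins","Northern region",149,0.01,0.01,0.01,0.01
"t3","Ins","Central region",29,0.01,0.01,0.01,0.02
"t3","Ins","Eastern region",92,0.01,0,0.01,0.01
"t3","Ins","Southern region",20,0.01,0,0.01,0.01
"t3","Econd","Western region",114,0.32,0.19,0.29,0.36
"t3","Econd","Belgrade",205,0.38,0.26,0.34,0.41
"t3","Econd","Northern region",149,0.36,0.23,0.33,0.4
"t3","Econd","Central region",29,0.37,0.29,0.26,0.48
"t3","Econd","Eastern region",92,0.39,0.24,0.34,0.44
"t3","Econd","Southern region",20,0.44,0.35,0.27,0.6
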