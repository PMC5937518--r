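label,region,n,A+,A-,B+,B-,AB+,AB-,O+,O-
0-9,age,27173,26.97,1.52,9.16,0.45,1.84,0.07,57.37,2.63
10-19,age,60297,25.80,1.17,8.51,0.41,1.65,0.07,59.97,2.42
20-29,age,101507,25.40,1.28,8.26,0.36,1.62,0.11,60.44,2.52
30-39,age,43134,26.15,1.46,8.25,0.39,1.69,0.11,59.29,2.65
40-49,age,17065,27.15,1.42,9.21,0.44,1.88,0.10,57.06,2.74
50-59,age,10085,28.60,1.57,8.90,0.58,2.00,0.13,55.54,2.69
60-69,age,6859,27.69,1.71,9.36,0.54,2.19,0.15,55.59,2.78
70-79,age,3742,27.53,1.79,9.25,0.53,2.08,0.16,55.72,2.94
80-90,age,1302,25.81,2.23,7.37,0.46,2.07,0.08,59.14,2.84
Female,gender,189482,25.74,1.33,8.48,0.40,1.66,0.09,59.78,2.52
Male,gender,81682,26.88,1.40,8.64,0.43,1.84,0.11,58.04,2.67
Total,total,271164,26.08,1.35,8.53,0.40,1.71,0.10,59.26,2.56
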