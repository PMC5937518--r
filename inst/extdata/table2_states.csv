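label,region,n,A+,A-,B+,B-,AB+,AB-,O+,O-
Baja California,Northwest,45716,27.36,1.43,8.64,0.39,1.82,0.10,57.58,2.67
Sonora,Northwest,14479,28.29,2.19,8.56,0.55,1.71,0.13,54.97,3.61
Sinaloa,Northwest,40449,30.52,2.41,7.94,0.62,1.93,0.12,52.73,3.73
Durango,Northwest,4925,25.75,1.14,10.86,0.47,2.40,0.10,56.20,3.09
Coahuila,Northeast,19823,22.67,0.82,8.68,0.33,1.28,0.05,64.05,2.12
Nuevo Leon,Northeast,921,24.86,0.76,9.88,0.22,1.85,0.00,59.50,2.93
Nayarit,West,5270,28.60,1.02,8.69,0.63,1.76,0.09,56.70,2.50
Jalisco,West,29206,28.18,1.77,9.31,0.47,2.24,0.18,54.86,2.99
Michoacan,West,2477,28.10,1.41,8.60,0.44,2.22,0.24,56.64,2.34
Puebla,East,6212,18.34,0.39,5.97,0.08,0.85,0.02,73.15,1.21
Veracruz,East,1790,21.34,0.56,8.72,0.22,1.28,0.06,65.75,2.07
San Luis Potosi,North-center,618,23.95,0.32,7.12,0.16,0.97,0.00,66.18,1.29
Aguascalientes,North-center,11709,25.13,1.12,9.90,0.38,1.96,0.09,58.87,2.55
Guanajuato,North-center,41648,25.85,0.98,8.98,0.35,1.78,0.07,59.78,2.20
Queretaro,North-center,9402,22.86,0.74,9.04,0.36,1.23,0.05,64.26,1.45
Estado de Mexico,South-center,22275,20.48,0.63,7.00,0.18,1.02,0.02,69.32,1.36
Ciudad de Mexico,South-center,14244,22.96,0.74,7.76,0.28,1.43,0.11,64.87,1.85
Total,All,271164,26.08,1.35,8.53,0.40,1.71,0.10,59.26,2.56
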