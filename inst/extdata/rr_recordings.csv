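day,mt,rat_id,mean_edr,mean_cam,rel_error,abs_error
Day2,MT3,R1,96.28,99.56,3.41,3.28
Day2,MT3,R2,79.08,98.63,24.72,19.55
Day2,MT3,R3,91.34,103.23,13.02,11.89
Day2,MT4,R1,94.05,80.29,14.63,13.76
Day2,MT4,R2,85.55,97.73,14.24,12.18
Day2,MT4,R3,94.97,96.83,1.96,1.86
Day3,MT1,R1,94.61,92.88,1.83,1.73
Day3,MT1,R2,90.69,82.72,8.79,7.97
Day3,MT1,R3,89.70,91.45,1.95,1.75
Day3,MT2,R1,96.28,91.64,4.82,4.64
Day3,MT2,R2,93.45,90.37,3.30,3.08
Day3,MT2,R3,89.27,87.77,1.68,1.50
Day3,MT3,R1,98.73,99.01,0.28,0.28
Day3,MT3,R2,96.32,103.90,7.87,7.58
Day3,MT3,R3,90.27,91.15,0.97,0.88
Day3,MT4,R1,98.87,89.18,9.80,9.69
Day3,MT4,R2,92.41,88.86,3.84,3.55
Day3,MT4,R3,90.60,95.97,5.93,5.37
Day4,MT1,R1,97.40,90.03,7.57,7.37
Day4,MT1,R2,89.80,87.75,2.33,2.09
Day4,MT1,R3,90.34,98.22,8.72,7.88
Day4,MT2,R1,92.79,92.75,0.04,0.04
Day4,MT2,R2,92.74,91.49,1.35,1.25
Day4,MT2,R3,90.55,92.68,2.35,2.13
Day4,MT3,R1,97.29,97.04,0.26,0.25
Day4,MT3,R2,84.80,93.48,10.24,8.68
Day4,MT3,R3,91.48,97.03,6.07,5.55
Day4,MT4,R1,89.24,88.32,1.03,0.92
Day4,MT4,R2,89.74,87.41,2.60,2.33
Day4,MT4,R3,87.79,93.49,6.49,5.70
Day5,MT1,R1,98.03,93.67,4.45,4.36
Day5,MT1,R2,93.69,86.25,7.94,7.44
Day5,MT1,R3,93.89,98.20,4.59,4.31
Day5,MT2,R1,93.86,91.41,2.61,2.45
Day5,MT2,R2,85.30,86.09,0.93,0.79
Day5,MT2,R3,93.95,89.95,4.26,4.00
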