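start_age,strategy,cost_millions,ly_10k,qaly_10k,icer,dominant
50,0,2850.60,131.68,131.34,NA,0
50,1,2178.78,131.24,130.95,170916.70,0
50,2,2466.19,133.09,132.82,-26039.00,1
50,3,2162.75,131.36,131.07,255943.68,0
50,4,2711.3,131.39,131.07,51816.20,0
50,5,2169.29,131.23,130.94,169106.85,0
50,6,2337.47,132.86,132.61,-40517.15,1
50,7,2154.25,131.35,131.07,253821.97,0
55,0,2624.19,117.02,116.66,NA,0
55,1,2064.38,116.55,116.25,136073.86,0
55,2,2303.03,118.16,117.86,-26795.85,1
55,3,2044.98,116.68,116.38,205164.59,0
55,4,2504.53,116.71,116.37,41735.56,0
55,5,2053.65,116.54,116.23,133629.86,0
55,6,2191.01,117.9,117.62,-44883.22,1
55,7,2035.40,116.67,116.37,201037.86,0
60,0,2294.40,100.21,99.85,NA,0
60,1,1856.28,99.76,99.45,110764.01,0
60,2,2056.71,100.96,100.65,-29686.70,1
60,3,1830.93,99.89,99.60,184393.06,0
60,4,2199.91,99.90,99.57,33469.96,0
60,5,1844.61,99.73,99.43,107694.64,0
60,6,1966.45,100.69,100.41,-58563.85,1
60,7,1820.56,99.88,99.58,177400.98,0
65,0,1865.10,81.30,80.97,NA,0
65,1,1554.41,80.92,80.64,93276.04,0
65,2,1709.14,81.66,81.37,-39002.09,1
65,3,1538.04,80.99,80.72,126336.89,0
65,4,1299.61,81.03,80.73,26858.57,0
65,5,1130.39,80.89,80.61,89011.27,0
65,6,1205.02,81.43,81.16,-121641.99,1
65,7,1526.50,80.96,80.69,119028.39,0
70,0,1799.12,59.76,59.51,NA,0
70,1,1542.15,59.53,59.31,82105.77,0
70,2,1644.69,59.91,59.68,-56880.33,1
70,3,1538.04,59.58,59.36,122600.49,0
70,4,1266.90,59.58,59.35,19748.11,0
70,5,1117.97,59.49,59.27,75360.72,0
70,6,1171.92,59.74,59.53,-793995.17,1
70,7,1100.09,59.36,59.33,108465.86,0
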