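pH,EC,N,P,K,Lat,Long,Crops,"District, year",Season,Temperature,Rainfall,Area,Production,Yield,Soil,pH,EC
7.3,2.8,252,5.1,77.28,14.4212,76.5546,Jowar,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,7.3,2.8
7.64,0.5,273,7.69,93.02,14.4252,76.5226,Jowar,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,7.64,0.5
7.88,2.2,224,4.18,67.68,14.4004,76.4306,Jowar,DAVANAC 2015-201,Summer,24.4167,91.9167,19327.6,62160.7,2173.45,Loam,7.88,2.2
7.78,1.33,203,7.23,76.92,14.3342,76.1875,Cowpea,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,7.78,1.33
7.74,3.8,224,3.09,47.02,14.2341,76.1157,Maize,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Maize,7.74,3.8
6.83,0.36,182,12.08,58.03,14.2286,76.1075,Jowar,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay,6.83,0.36
8.27,0.26,238,5.13,96.86,14.2197,76.1154,Paddy,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,8.27,0.26
8.15,0.45,203,8.36,86.97,14.2005,75.7819,Maize,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay,8.15,0.45
5.74,0.46,350,21.6,101.76,14.2149,75.7171,Paddy,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay,5.74,0.46
5.07,0.13,336,30.4,78.62,14.2252,75.7335,Paddy,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay,5.07,0.13
8.52,0.32,182,5.41,87.31,14.2192,75.6752,Maize,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Loam,8.52,0.32
8.12,0.16,259,6.8,102.67,14.3234,75.7593,Paddy,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Red,8.12,0.16
8.3,0.28,273,6.17,57.64,14.308,75.7424,Cowpea,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Red,8.3,0.28
8.9,0.22,210,5.08,47.85,14.3364,75.7416,Groundnut,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Red,8.9,0.22
8.2,0.21,301,7.61,120.48,14.4354,75.7647,Groundnut,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,8.2,0.21
8.49,1.2,280,7.1,67.68,14.3327,75.7777,Groundnut,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,8.49,1.2
8.28,0.42,245,4.81,91.1,14.3078,75.7611,Jowar,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,8.28,0.42
8.3,0.16,231,4.18,76.99,14.5853,75.6677,Groundnut,DAVANAC 2015-201,Summer,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay,8.3,0.16
7.27,0.48,224,13.16,119.66,14.6048,75.6487,Maize,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Red,7.27,0.48
7.88,0.31,266,10.08,98.11,14.5125,75.9491,Paddy,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,7.88,0.31
7.8,0.41,294,9.17,50.64,14.5545,75.755,Groundnut,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,7.8,0.41
8.18,1.25,231,5.03,104.68,14.5639,75.7905,Paddy,DAVANAC 2015-201,Rabi,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Red,8.18,1.25
7.6,0.45,203,13.77,55.1,14.5767,75.8214,Cowpea,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,7.6,0.45
7.9,4.8,245,7.68,77.42,14.5904,75.8366,Jowar,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Sandy,7.9,4.8
7.88,0.31,266,10.08,98.11,14.5125,75.9491,Paddy,DAVANAC 2015-201,Kharif,24.4167,91.9167,"19,327.6","62,160.7",2173.45,Clay loam,7.88,0.31
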