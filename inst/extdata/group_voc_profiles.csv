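group,condition,compound,mean_mg_per_L
control,aerobic,ammonia,0.654
control,aerobic,acetaldehyde,0.056
control,aerobic,acetone,0.016
control,aerobic,methanol,0.089
control,aerobic,ethanol,0.114
control,aerobic,acetic_acid,0.074
control,anaerobic,ammonia,0.566
control,anaerobic,acetaldehyde,0.006
control,anaerobic,acetone,0.069
control,anaerobic,methanol,0.050
control,anaerobic,ethanol,0.368
control,anaerobic,acetic_acid,0.098
1,aerobic,ammonia,0.176
1,aerobic,acetaldehyde,0.130
1,aerobic,acetone,0.038
1,aerobic,methanol,0.036
1,aerobic,ethanol,0.057
1,aerobic,acetic_acid,0.119
1,aerobic,acetonitrile,0.162
1,aerobic,chloroform,1.826
1,aerobic,pentylamine|butyramide,0.02
1,aerobic,dipropylamine|pentanamide,0.01
1,anaerobic,ammonia,0.234
1,anaerobic,acetaldehyde,0.125
1,anaerobic,acetone,0.393
1,anaerobic,methanol,0.019
1,anaerobic,ethanol,0.014
1,anaerobic,acetic_acid,0.057
1,anaerobic,acetonitrile,0.299
1,anaerobic,chloroform,1.038
1,anaerobic,pentylamine|butyramide,0.02
1,anaerobic,dipropylamine|pentanamide,0.01
2,aerobic,ammonia,0.409
2,aerobic,acetaldehyde,0.048
2,aerobic,acetone,0.052
2,aerobic,methanol,0.091
2,aerobic,ethanol,0.011
2,aerobic,acetic_acid,0.043
2,aerobic,acetonitrile,0.174
2,aerobic,chloroform,1.061
2,aerobic,pentylamine|butyramide,0.04
2,aerobic,dipropylamine|pentanamide,0.02
2,anaerobic,ammonia,0.236
2,anaerobic,acetaldehyde,0.045
2,anaerobic,acetone,0.189
2,anaerobic,methanol,0
2,anaerobic,ethanol,0.003
2,anaerobic,acetic_acid,0.058
2,anaerobic,acetonitrile,0.272
2,anaerobic,chloroform,1.292
2,anaerobic,pentylamine|butyramide,0.04
2,anaerobic,dipropylamine|pentanamide,0.02
3,aerobic,ammonia,0.152
3,aerobic,acetaldehyde,0.128
3,aerobic,acetone,0.183
3,aerobic,methanol,0.045
3,aerobic,ethanol,0.051
3,aerobic,acetic_acid,0.060
3,aerobic,acetonitrile,0.400
3,aerobic,chloroform,2.767
3,aerobic,pentylamine|butyramide,0.04
3,aerobic,dipropylamine|pentanamide,0.02
3,anaerobic,ammonia,0.284
3,anaerobic,acetaldehyde,0.048
3,anaerobic,acetone,0.693
3,anaerobic,methanol,0.161
3,anaerobic,ethanol,0.041
3,anaerobic,acetic_acid,0.131
3,anaerobic,acetonitrile,0.653
3,anaerobic,chloroform,2.072
3,anaerobic,pentylamine|butyramide,0.04
3,anaerobic,dipropylamine|pentanamide,0.02
4,aerobic,ammonia,5.563
4,aerobic,acetaldehyde,0.825
4,aerobic,acetone,0.046
4,aerobic,methanol,0.100
4,aerobic,ethanol,0.093
4,aerobic,acetic_acid,0.053
4,aerobic,acetonitrile,0.316
4,aerobic,chloroform,3.474
4,aerobic,pentylamine|butyramide,0.02
4,aerobic,dipropylamine|pentanamide,0.01
4,anaerobic,ammonia,6.664
4,anaerobic,acetaldehyde,1.023
4,anaerobic,acetone,0.046
4,anaerobic,methanol,0.214
4,anaerobic,ethanol,0.130
4,anaerobic,acetic_acid,0.102
4,anaerobic,acetonitrile,0.200
4,anaerobic,chloroform,2.622
4,anaerobic,pentylamine|butyramide,0.02
4,anaerobic,dipropylamine|pentanamide,0.01
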