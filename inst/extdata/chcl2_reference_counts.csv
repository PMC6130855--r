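group,condition,mz83,mz85,mz87,pct83,pct85,pct87,chcl3_mg_per_L
control,aerobic,n/d,n/d,n/d,n/d,n/d,n/d,n/d
control,anaerobic,n/d,n/d,n/d,n/d,n/d,n/d,n/d
1,aerobic,931,487,112,61,32,7,1.826
1,anaerobic,505,332,95,54,37,10,1.038
2,aerobic,445,333,80,52,39,9,1.061
2,anaerobic,655,398,60,59,36,5,1.292
3,aerobic,1092,935,245,48,41,11,2.767
3,anaerobic,1372,783,150,59,34,6,2.072
4,aerobic,1644,1342,152,52,43,5,3.474
4,anaerobic,1485,983,97,58,38,4,2.622
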