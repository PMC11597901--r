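joint,speed,measure,bias,loa_low,loa_high,r
knee,0.7,max,5.04,-2.47,12.56,0.58
knee,0.7,min,-2.54,-5.39,0.30,0.90
knee,0.7,rom,7.59,-2.05,17.23,0.50
knee,1.0,max,3.86,-4.37,12.08,0.45
knee,1.0,min,-3.43,-6.37,-0.48,0.91
knee,1.0,rom,7.28,-2.83,17.39,0.54
knee,1.3,max,2.46,-3.72,8.63,0.73
knee,1.3,min,-3.90,-6.34,-1.47,0.94
knee,1.3,rom,6.36,-0.95,13.67,0.65
hip,0.7,max,4.23,2.34,6.12,0.96
hip,0.7,min,-5.19,-7.67,-2.72,0.95
hip,0.7,rom,9.42,5.61,13.23,0.81
hip,1.0,max,4.49,2.10,6.89,0.94
hip,1.0,min,-6.33,-9.75,-2.92,0.89
hip,1.0,rom,10.82,5.60,16.05,0.53
hip,1.3,max,5.64,2.38,8.90,0.89
hip,1.3,min,-7.03,-10.73,-3.33,0.86
hip,1.3,rom,12.67,6.83,18.51,0.52
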