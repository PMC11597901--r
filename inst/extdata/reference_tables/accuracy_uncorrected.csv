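joint,speed,measure,bias,loa_low,loa_high,r
knee,0.7,max,9.2,0.3,18.0,0.41
knee,0.7,min,1.6,-3.2,6.5,0.70
knee,0.7,rom,7.6,-2.0,17.2,0.50
knee,1.0,max,8.2,-1.6,18.0,0.46
knee,1.0,min,0.9,-2.5,4.3,0.93
knee,1.0,rom,7.2,-2.8,17.4,0.54
knee,1.3,max,7.0,0.1,13.9,0.63
knee,1.3,min,0.6,-3.9,5.2,0.71
knee,1.3,rom,6.4,-1.0,13.7,0.65
hip,0.7,max,6.1,-2.0,14.2,0.14
hip,0.7,min,-3.3,-12.1,5.4,0.29
hip,0.7,rom,9.4,5.6,13.2,0.81
hip,1.0,max,5.7,-2.8,14.2,0.19
hip,1.0,min,-5.1,-13.4,3.1,0.13
hip,1.0,rom,10.8,5.6,16.0,0.53
hip,1.3,max,6.9,-1.5,15.4,0.28
hip,1.3,min,-5.7,-13.7,2.2,0.14
hip,1.3,rom,12.7,6.8,18.5,0.52
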