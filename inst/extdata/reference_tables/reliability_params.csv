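joint,speed,measure,icc,icc_ci_low,icc_ci_high,sem,mdc
knee,0.7,max,0.85,0.63,0.95,1.78,2.46
knee,0.7,min,0.85,0.61,0.95,0.66,0.92
knee,0.7,rom,0.85,0.63,0.95,1.85,2.56
knee,1.0,max,0.82,0.49,0.94,1.85,2.56
knee,1.0,min,0.86,0.64,0.95,0.80,1.11
knee,1.0,rom,0.81,0.48,0.93,2.20,3.00
knee,1.3,max,0.86,0.59,0.96,1.60,2.22
knee,1.3,min,0.61,0.14,0.85,1.19,1.64
knee,1.3,rom,0.82,0.53,0.93,2.00,2.77
hip,0.7,max,0.90,0.74,0.97,1.01,1.40
hip,0.7,min,0.84,0.57,0.94,1.37,1.90
hip,0.7,rom,0.80,0.52,0.93,1.26,1.74
hip,1.0,max,0.94,0.83,0.98,0.83,1.15
hip,1.0,min,0.77,0.44,0.92,1.22,1.69
hip,1.0,rom,0.80,0.50,0.93,1.47,2.04
hip,1.3,max,0.90,0.71,0.97,1.05,1.45
hip,1.3,min,0.78,0.46,0.92,1.05,1.45
hip,1.3,rom,0.84,0.59,0.94,1.02,1.41
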