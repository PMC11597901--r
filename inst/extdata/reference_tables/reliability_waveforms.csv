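joint,speed,rmse_mean,rmse_sd,lcc,lcc_ci_low,lcc_ci_high
knee,0.7,2.34,0.90,0.96,0.93,0.99
knee,1.0,2.20,0.97,0.99,0.98,0.99
knee,1.3,2.42,1.44,0.98,0.97,1.00
hip,0.7,1.80,0.82,0.98,0.98,0.99
hip,1.0,1.49,0.60,0.98,0.97,0.99
hip,1.3,1.80,1.18,0.98,0.96,0.99
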