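daf,a,ssc,ta,edible_rate,rot_rate,score_reported
90,0.00,0.00,0.00,0.00,0.37,0.07
97,0.38,0.76,0.00,0.71,0.33,0.44
104,0.60,0.62,1.00,1.00,1.00,0.84
111,1.00,1.00,1.00,0.71,0.00,0.74
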