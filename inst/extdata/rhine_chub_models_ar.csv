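model,predictor,slope,r2,daic,weight
i,distance,-0.004,0.096,26.543,0.000
ii,distance,0.009,0.440,6.062,0.041
ii,all_barriers,-0.151,0.440,6.062,0.041
iii,distance,0.009,0.481,4.483,0.091
iii,fishpass,-0.152,0.481,4.483,0.091
iii,no_fishpass_incl_falls,-0.322,0.481,4.483,0.091
iv,distance,-0.004,0.153,25.511,0.000
iv,falls,0.478,0.153,25.511,0.000
v,distance,0.009,0.440,8.058,0.015
v,falls,-0.134,0.440,8.058,0.015
v,other_barriers,-0.150,0.440,8.058,0.015
vi,distance,0.005,0.548,0.000,0.853
vi,falls,0.349,0.548,0.000,0.853
vi,fishpass,-0.109,0.548,0.000,0.853
vi,no_fishpass,-0.544,0.548,0.000,0.853
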