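model,predictor,slope,r2,daic,weight
i,distance,2.731e-4,0.354,10.657,0.003
ii,distance,1.243e-4,0.404,8.857,0.007
ii,all_barriers,1.974e-3,0.404,8.857,0.007
iii,distance,1.122e-4,0.527,0.000,0.550
iii,fishpass,1.392e-3,0.527,0.000,0.550
iii,no_fishpass_incl_falls,1.149e-2,0.527,0.000,0.550
iv,distance,2.319e-4,0.423,7.358,0.014
iv,falls,1.878e-2,0.423,7.358,0.014
v,distance,3.904e-5,0.498,2.783,0.137
v,falls,2.476e-2,0.498,2.783,0.137
v,other_barriers,2.458e-3,0.498,2.783,0.137
vi,distance,8.191e-5,0.534,1.277,0.290
vi,falls,1.808e-2,0.534,1.277,0.290
vi,fishpass,1.720e-3,0.534,1.277,0.290
vi,no_fishpass,9.402e-3,0.534,1.277,0.290
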